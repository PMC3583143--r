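Package: omicsTrio
Title: Integrative Analysis of Genotype, DNA Methylation and Gene Expression
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for jointly analysing SNP genotypes, DNA methylation and
    gene expression measured on the same cohort. Implements covariate-adjusted
    cis/trans methylation-expression association scanning with split
    FDR/Bonferroni correction, mQTL/eQTL mapping with LD pruning and
    independent-locus counting, CpG island/shore enrichment via Fisher's exact
    test, causal orientation of SNP-methylation-expression triples by
    maximum-likelihood structural equation models and local edge orienting
    (LEO) scores, and weighted correlation network analysis (soft-thresholded
    adjacency, topological overlap, module eigengenes, module membership,
    cross-data module matching and permutation Zsummary/medianRank module
    preservation). A synthetic cohort generator with planted causal triples,
    cis/trans effects and module structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: DNAMethylation, GeneExpression, SNP, NetworkInference,
    GraphAndNetwork, Epigenetics, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
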