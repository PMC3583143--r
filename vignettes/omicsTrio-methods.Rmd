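---
title: "omicsTrio: models, design choices and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omicsTrio: models, design choices and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`omicsTrio` analyses matched SNP genotype, DNA methylation and gene
expression matrices from one cohort.  This vignette is the package's own
account of the statistical machinery: the models and their assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the underlying methods
leave room.

## Data model

All matrices are probes × samples.  `OmicsSet` (a `SummarizedExperiment`)
holds one layer — methylation beta values in [0, 1] or log2 expression —
with probe coordinates (chromosome, 1-based bp) in `rowData` and sample
covariates (age in years, sex coded 0/1) in `colData`.  `GenotypeSet` holds
additive ALT-allele dosages in [0, 2] (fractional imputed dosages allowed,
never rounded) with the minor allele frequency recomputed from the dosages.
CpG islands enter as BED (0-based half-open) and are converted once, at
read time, to the package-wide internal convention of 1-based closed
intervals; all distance arithmetic happens in that one convention.  Sample
order is taken from the covariates table and enforced when layers are
aligned.  Missing values are rejected by every reader: the downstream
models assume complete cases, and silent imputation would change their
meaning.

## Association scans

The scan regresses expression (dependent) on methylation (independent)
with age and sex as covariates, by ordinary least squares; the Wald t-test
of the methylation coefficient on n − p degrees of freedom is the test.
Internally the scan residualizes both matrices on [intercept, age, sex]
with one QR decomposition and works with cross-correlations of residuals —
by Frisch–Waugh–Lovell this is algebraically identical to the full
regression, which the tests assert against `lm()` to 1e-10.

Conventions, all configurable in `analysisConfig()`:

* **cis window** (`cisWindowBp`, default 500000 bp): same chromosome and
  point-to-point probe distance at most the window, *boundary inclusive*.
  The inclusive reading is asserted in tests (distance exactly 500 kb is
  cis).
* **cis correction**: Benjamini–Hochberg FDR pooled over *all* enumerated
  cis tests, significant at q ≤ `fdrQ` (0.05).  Pooling is the stricter
  and simpler alternative to per-probe FDR.
* **trans correction**: Bonferroni with the full probe product
  n_meth × n_expr, not the number of enumerated tests — deliberately
  conservative, matching the convention of correcting for the whole search
  space.  Only significant trans records are materialized, so the
  exhaustive trans search stays memory-bounded (`transMaxPairs` can cap it
  further with seeded uniform subsampling).
* **sign**: positive/negative from the coefficient sign; the adjusted R²
  reported is that of the full model including covariates.

The QTL scan reuses the same code path with dosage as predictor (the tests
assert record-level equality with `linearAssociation`).  SNPs are filtered
to MAF ≥ `mafMin` (0.05) first.  Cis QTL significance is 0.05 / n_probes —
the probe count only, not probes × SNPs; the stricter product threshold
applies to the (off-by-default) trans scan.  LD pruning is greedy and
windowed: within a sliding window (50 SNPs, step 5, ordered by position),
any pair with r² > 0.2 loses its later-positioned member, repeatedly; this
tie-break makes the prune deterministic for a given input.

## CpG island / shore classification

A probe is *island* if its position overlaps an island interval, *shore* if
it lies within `shoreBp` (2000 bp) of an island boundary — inclusive at
exactly 2000 — and *outside* otherwise.  One subtlety is worth recording:
`GenomicRanges::distance()` returns 0 both for overlap and for direct
adjacency, so island membership is decided by overlap and the shore
condition reads `distance ≤ shoreBp − 1` (a probe g ≥ 1 bases past a
boundary has distance g − 1).  Enrichment uses the two-sided Fisher exact
test with the probability-mass rule (sum of hypergeometric probabilities no
larger than the observed table's), tested against exhaustive enumeration;
the odds ratio reported is the sample odds ratio ad/bc, with Inf allowed.
Each region class is tested as its own 2×2 table (class vs rest), and the
background is the full annotated probe universe — the array manifest, not
the QC-passed subset — without foreground subtraction.

## Causal scoring: five SEMs and the LEO score

For a triple (S, M, E) the five candidate models are the two chains
S→M→E and S→E→M, the common cause M←S→E, and the two colliders S→E←M and
S→M←E.  Each has five free parameters against six covariance moments, so
each carries one testable constraint: a vanishing partial correlation for
the chains and common cause, a vanishing marginal covariance for the
colliders.  The fit is by maximum likelihood on the sample covariance:
minimize F = ln|Σ(θ)| + tr(S Σ⁻¹) − ln|S| − 3, χ² = (n−1)·F_min, p from
χ²₁.  Numerical conventions:

* variances are optimized on the log scale (positivity without
  constraints);
* the start is an analytic moment-matching estimate, followed by BFGS and
  a Nelder–Mead polish, with deterministic jittered restarts
  (`nStarts = 5`);
* convergence is declared when a central-difference gradient check finds
  no descent direction (norm below 1e-4 relative); non-converged fits
  propagate as flagged results with p = NA and are excluded downstream
  rather than silently treated as p = 0;
* the (n−1) multiplier is the classical discrepancy convention
  (configurable to n);
* fits are scale-invariant (multiplying M or E by a positive constant
  leaves every χ² unchanged), so no standardization is imposed — asserted
  numerically in the tests.

For every model the df = 1 constraint admits a closed-form likelihood-ratio
statistic, −(n−1)·ln(1 − r²) of the relevant partial or marginal
correlation.  The package deliberately ships the *numerical* fit (it
generalizes, returns parameter estimates, and flags non-convergence), and
the closed forms serve as independent oracles in the tests, which require
1% relative agreement over random positive-definite inputs.

The LEO score of a focal model is log10 of its fit p over the best
competing fit p.  The denominator includes all four competitors by default
(`competing = "all"`); a restricted mode keeps only the two chain models.
Scores above `leoThreshold` (0.8) count as support.  The SNP enters raw
(genotypes are fixed; they cannot be caused by M or E), while M and E are
first residualized on age and sex.  Triples are screened so the anchor SNP
is significantly cis-associated with both the methylation and the
expression probe, and results are keyed by (SNP, M, E) — never aggregated
across anchors, because one gene can legitimately carry different
directions at different anchor SNPs.

## Network modules and preservation

Adjacency is |cor|^β (unsigned, default) or ((1+cor)/2)^β (signed).  The
soft power is either fixed or chosen as the smallest candidate whose
scale-free fit R² (log–log regression of binned connectivity frequency)
reaches 0.8, falling back with a warning to the best-fitting candidate.
The topological overlap measure TOM_ij = (Σ_u a_iu a_uj + a_ij) /
(min(k_i, k_j) + 1 − a_ij) feeds average-linkage clustering on 1 − TOM.

Module detection uses a *static* cut at a quantile of the merge heights
(default 0.8) rather than a dynamic branch cut — a deliberate
simplification that is deterministic and adequate for block-structured
data.  The default was fixed by a pilot over seeds of the two-block design
(sizes 50/40, within-correlation 0.8, 100 noise probes): 0.8 recovers both
blocks with full member recall while higher quantiles let average linkage
chain background probes onto modules and eventually merge them.  Clusters
below `minModuleSize` (30, consistent with the smallest modules the method
is meant to find) become background (label 0); labels are ordered by
decreasing size, module 1 largest.

Eigengenes are the first right singular vector of the module's row-z-scored
matrix (unit norm), sign-oriented so members' mean correlation with their
eigengene is positive; kME is the correlation of *every* probe with every
eigengene, enabling cross-assignment tables.  Cross-dataset module matching
cross-tabulates labelings on the shared feature universe with one-sided
Fisher overlap tests and greedily assigns each test module the reference
label of its most significant overlap (p < 0.05, each reference label used
once); unmatched modules get fresh labels above the reference range.
Because the two layers measure different probes, the pipeline performs
matching and preservation at gene level, keeping the first probe per gene
symbol.

Module preservation follows the permutation scheme: for each reference
module, two density statistics (mean test adjacency within the module;
variance explained by the module's test eigengene) and three connectivity
statistics (reference–test correlation of intramodular connectivity, of
kME, and of the vectorized within-module correlations) are compared with
the same statistics on random probe sets of equal size.  Z per statistic,
medians within class, Zsummary the mean of Zdensity and Zconnectivity,
interpreted with the usual bands (< 2 none, 2–10 weak/moderate, > 10
strong); medianRank is the median across statistics of the module's rank.
Degenerate case: when a statistic has zero permutation variance — with
ref = test every connectivity correlation is exactly 1 for any probe set —
its Z is undefined and drops out of the class median; if an entire class is
degenerate, Zsummary falls back to the informative class.  Coercing those
components to 0 would instead halve the self-preservation Z of a genuinely
dense module, which is why the convention matters.

Robust eigengene correlation is the biweight midcorrelation (tuning
constant 9, weights vanish beyond 9 MADs), with p-values from the Student-t
approximation on n − 2 df and a Pearson fallback (with warning) for
zero-MAD inputs.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` generates the study conditions end to end: 148 samples
(72 male, 76 female), age uniform on 19–88; a toy genome of two 10 Mb
chromosomes with 1 kb CpG islands every 50 kb; 500 HWE SNPs with MAF
uniform on [0.05, 0.5]; 2000 methylation and 2000 expression probes.
Methylation is built on a latent Gaussian scale and mapped through the
logistic function, so beta values are legal while linear-model assumptions
hold on the latent scale where effects are planted.  Planted structure:

* cis pairs with latent explained variance uniform on [0.05, 0.5] (a
  plausible range for local regulation) and 65% negative; trans pairs with
  R² on [0.23, 0.6] and 68% positive — trans effects that survive a
  probe-product Bonferroni are necessarily large;
* causal triples per model via `simulateCausalTriple()` — chains and
  common cause as M = a·S′ + ε with unit-variance normalization (requiring
  |a|, |b| < 1), colliders requiring a² + b² < 1, with S′ the dosage
  standardized by its theoretical HWE moments;
* modules as one latent factor per module
  (x = √w·f + √(1−w)·noise, within-correlation w = 0.6 by default), with
  optional factors shared across layers over *disjoint* probe sets — the
  construction behind "correlated eigengenes without gene overlap";
* gene symbols drawn for both layers from one shared pool at random, so
  cross-layer gene overlap of planted modules is hypergeometric-null;
* optional age/sex confounding injected into both members of planted
  pairs, to verify that covariate adjustment removes it, and an optional
  shore bias for SNP-driven methylation probes to exercise the enrichment
  machinery.

Randomness is R's default Mersenne-Twister; one seed makes the full output
byte-reproducible, and the pipeline fans a single config seed out to
per-stage child seeds through a fixed affine map so stages are
independently reproducible.

What the generator does *not* emulate: realistic LD beyond what duplicated
or correlated dosage columns provide, imputation dosage uncertainty, array
batch effects, cell-type composition, bimodal beta distributions at
extreme probes, or hub-and-spoke scale-free topology beyond what latent
factors induce.  Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
every artefact of real array data.

## QC stages

Beta values are M/(M+U), with zero total intensity an error rather than an
imputed value.  Quantile normalization delegates to
`limma::normalizeQuantiles` (ties share mean quantiles; idempotent).
Detection filtering removes samples first (detection p > 0.01 in more than
1% of probes), then probes (p > 0.01 in more than 1% of remaining
samples), both thresholds strict and exposed.  Inter-array outliers are
flagged by the standardized connectivity Z.k = standardized Σ_{j≠i}
cor(i, j), Pearson correlations, threshold −3; a zero connectivity spread
yields no flags, and constant sample vectors are an error naming the
sample.  Probes whose 50 bp span (configurable; typical probe length)
contains a SNP with MAF > 1% are removed when a SNP list is supplied.

## Problem sizes in the shipped tests

The suite exercises: SEM oracle agreement on 100 random covariances × 5
models at n = 148; direction recovery on 200 simulated chain-model cohorts
of n = 148 (pass thresholds frozen from a pilot: ≥ 75% best-model rate,
≥ 80% direction accuracy at the 0.8 LEO threshold); null FDR calibration
on 200 global-null scans of 32 × 32 probes at n = 100; SEM fit p
uniformity on 500 triples at n = 2000; module recovery on the 50/40
two-block design at n = 200; preservation with 100 permutations; and an
end-to-end pipeline on a 60-sample, 300 + 300-probe cohort.  These sizes
were chosen to make every property measurable with comfortable margins
while keeping the default test run quick on one core.

## Known limitations

* The static tree cut can attach weakly correlated background probes to
  large modules; a dynamic hybrid cut would be sharper but
  non-deterministic across implementations.
* The LEO analysis is single-marker: multi-marker anchors and latent
  variable SEMs are out of scope.
* Fisher-based module matching is greedy; a global assignment could differ
  when overlaps are nearly tied.
* The trans Bonferroni uses the full probe product even when enumeration
  is capped, which is conservative by construction.
* p-values from the biweight midcorrelation use the t approximation, which
  is approximate at small n.
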