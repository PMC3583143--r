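#' @import methods
#' @importFrom stats cor cov median mad sd quantile rnorm rbinom runif
#'   pchisq pt qt plogis fisher.test p.adjust hclust cutree as.dist
#'   setNames optim aggregate
#' @importFrom utils read.table write.table head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end reduce
#' @importFrom IRanges IRanges
NULL

#' OmicsSet: a probes-by-samples molecular data matrix
#'
#' Container for one molecular data layer measured on a cohort: either
#' methylation beta values (fractions in \[0, 1\]) or log2 expression
#' intensities.  It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so probe annotation
#' (chromosome, 1-based position, gene symbol) lives in \code{rowData} and
#' sample covariates (age, sex) in \code{colData}.
#'
#' Validity rules: probe ids are unique, values contain no missing entries
#' (the analyses assume complete cases after QC), and beta values lie in
#' \[0, 1\].
#'
#' @slot kind character; \code{"methylation_beta"} or \code{"expression_log2"}.
#' @export
setClass("OmicsSet",
  contains = "SummarizedExperiment",
  slots = c(kind = "character")
)

setValidity("OmicsSet", function(object) {
  msg <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("methylation_beta", "expression_log2"))
    msg <- c(msg, "kind must be 'methylation_beta' or 'expression_log2'")
  if (!"values" %in% assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  else {
    v <- assay(object, "values")
    if (nrow(v) > 0 && anyNA(v))
      msg <- c(msg, "values contain missing entries; complete cases required")
    if (nrow(v) > 0 && identical(object@kind, "methylation_beta") &&
        !anyNA(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "methylation beta values must lie in [0, 1]")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "probe ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsSet
#'
#' @param values numeric matrix, probes in rows, samples in columns; both
#'   dimensions must be named.
#' @param kind \code{"methylation_beta"} or \code{"expression_log2"}.
#' @param annotation optional data.frame with columns \code{probe_id},
#'   \code{chrom}, \code{pos} (1-based bp) and \code{gene_symbol}; every probe
#'   must have exactly one row.
#' @param covariates optional data.frame with columns \code{sample_id},
#'   \code{age}, \code{sex}; sample order of the matrix is checked against it.
#' @return An \linkS4class{OmicsSet}.
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' OmicsSet(m, "methylation_beta")
#' @export
OmicsSet <- function(values, kind, annotation = NULL, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("probe ids (rownames) are required")
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("sample ids (colnames) are required")
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(annotation)) {
    annotation <- validateAnnotation(annotation)
    miss <- setdiff(rownames(values), annotation$probe_id)
    if (length(miss))
      stop("probes without annotation: ", paste(head(miss, 5), collapse = ", "))
    idx <- match(rownames(values), annotation$probe_id)
    rd <- DataFrame(chrom = annotation$chrom[idx],
                    pos = annotation$pos[idx],
                    gene_symbol = annotation$gene_symbol[idx],
                    row.names = rownames(values))
  }
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(covariates)) {
    covariates <- validateCovariates(covariates)
    if (!setequal(covariates$sample_id, colnames(values)))
      stop("covariate sample ids do not match matrix columns")
    idx <- match(colnames(values), covariates$sample_id)
    cd <- DataFrame(age = covariates$age[idx], sex = covariates$sex[idx],
                    row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(values = values),
                             rowData = rd, colData = cd)
  new("OmicsSet", se, kind = kind)
}

#' GenotypeSet: SNP dosages with coordinates and allele frequencies
#'
#' SNP-by-sample additive dosage matrix (expected ALT allele count in
#' \[0, 2\]; fractional imputed dosages allowed).  \code{rowData} carries the
#' SNP coordinates (\code{chrom}, \code{pos}) and the minor allele frequency
#' recomputed from the dosages.
#'
#' @export
setClass("GenotypeSet", contains = "SummarizedExperiment")

setValidity("GenotypeSet", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (nrow(d) > 0) {
    if (anyNA(d)) msg <- c(msg, "missing dosages are not supported")
    else if (min(d) < 0 || max(d) > 2)
      msg <- c(msg, "dosages must lie in [0, 2]")
    need <- c("chrom", "pos", "maf")
    if (!all(need %in% colnames(rowData(object))))
      msg <- c(msg, "rowData must contain chrom, pos, maf")
    else if (!anyNA(d)) {
      maf <- computeMaf(d)
      if (max(abs(maf - rowData(object)$maf)) > 1e-9)
        msg <- c(msg, "stored maf does not match dosage-derived maf")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeSet
#'
#' MAF is computed from the dosages as \code{min(p, 1 - p)} with
#' \code{p = mean(dosage) / 2}; monomorphic SNPs get MAF 0.
#'
#' @param dosage numeric matrix, SNPs in rows (named), samples in columns
#'   (named), entries in \[0, 2\].
#' @param chrom,pos SNP coordinates (1-based bp), one per row of
#'   \code{dosage}.
#' @return A \linkS4class{GenotypeSet}.
#' @export
GenotypeSet <- function(dosage, chrom, pos) {
  dosage <- as.matrix(dosage)
  rd <- DataFrame(chrom = as.character(chrom), pos = as.integer(pos),
                  maf = computeMaf(dosage), row.names = rownames(dosage))
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd)
  new("GenotypeSet", se)
}

# minor allele frequency from an additive dosage matrix (rows = SNPs)
computeMaf <- function(dosage) {
  if (nrow(dosage) == 0) return(numeric(0))
  p <- rowMeans(dosage) / 2
  pmin(p, 1 - p)
}

#' @describeIn OmicsSet the data kind of the layer
#' @param x an OmicsSet
#' @export
omicsKind <- function(x) x@kind

#' Probe annotation of an OmicsSet as a data.frame
#'
#' @param x an \linkS4class{OmicsSet} built with annotation.
#' @return data.frame with probe_id, chrom, pos, gene_symbol.
#' @export
probeAnnotation <- function(x) {
  rd <- rowData(x)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    stop("object carries no probe annotation")
  data.frame(probe_id = rownames(x), chrom = as.character(rd$chrom),
             pos = as.integer(rd$pos),
             gene_symbol = if ("gene_symbol" %in% colnames(rd))
               as.character(rd$gene_symbol) else NA_character_,
             stringsAsFactors = FALSE)
}

setMethod("show", "OmicsSet", function(object) {
  cat("OmicsSet (", object@kind, "): ", nrow(object), " probes x ",
      ncol(object), " samples\n", sep = "")
  if (ncol(rowData(object)) > 0)
    cat("  annotated: chrom/pos", if ("gene_symbol" %in%
        colnames(rowData(object))) "/gene_symbol", "\n", sep = "")
})

setMethod("show", "GenotypeSet", function(object) {
  cat("GenotypeSet: ", nrow(object), " SNPs x ", ncol(object), " samples\n",
      sep = "")
  if (nrow(object) > 0)
    cat("  MAF range: ", paste(signif(range(rowData(object)$maf), 3),
        collapse = " - "), "\n", sep = "")
})

validateAnnotation <- function(annotation) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(annotation)))
    stop("annotation requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe ids in annotation")
  if (any(annotation$pos < 1)) stop("annotation positions must be >= 1")
  if (!"gene_symbol" %in% colnames(annotation))
    annotation$gene_symbol <- NA_character_
  annotation
}

validateCovariates <- function(covariates) {
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% colnames(covariates)))
    stop("covariates require columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(covariates$sample_id))
    stop("duplicate sample ids in covariates")
  if (any(!is.finite(covariates$age)) || any(covariates$age < 0))
    stop("age must be finite and >= 0")
  if (!all(covariates$sex %in% c(0, 1)))
    stop("sex must be coded 0/1")
  covariates
}
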