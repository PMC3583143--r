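#' Read a genotype dosage matrix
#'
#' Two on-disk encodings are supported.  The TSV dialect has a header line
#' \code{snp_id chrom pos <sample ids...>} and one row per SNP with additive
#' ALT-allele dosages in \[0, 2\].  The VCF path uses
#' \pkg{VariantAnnotation} and converts each per-sample GT call to a dosage
#' by counting ALT alleles; missing genotypes are rejected because the
#' downstream models assume complete cases.
#'
#' @param path file path.
#' @param format "tsv" or "vcf".
#' @return A \linkS4class{GenotypeSet} with MAF recomputed from the dosages.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") readGenotypesTsv(path) else readGenotypesVcf(path)
}

readGenotypesTsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty genotype file: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4 || hdr[1] != "snp_id")
    stop("genotype TSV header must start with snp_id, chrom, pos")
  samples <- hdr[-(1:3)]
  nfield <- length(hdr)
  body <- lines[-1]
  ids <- character(length(body)); chrom <- character(length(body))
  pos <- integer(length(body))
  dose <- matrix(NA_real_, length(body), length(samples))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != nfield)
      stop(sprintf("malformed genotype row at line %d: expected %d fields, got %d",
                   i + 1L, nfield, length(f)))
    ids[i] <- f[1]; chrom[i] <- f[2]
    p <- suppressWarnings(as.integer(f[3]))
    if (is.na(p)) stop(sprintf("non-integer position at line %d", i + 1L))
    pos[i] <- p
    d <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(d)) stop(sprintf("non-numeric dosage at line %d", i + 1L))
    dose[i, ] <- d
  }
  if (length(body) && (min(dose) < 0 || max(dose) > 2))
    stop("dosage outside [0, 2]")
  dimnames(dose) <- list(ids, samples)
  GenotypeSet(dose, chrom, pos)
}

readGenotypesVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dose <- apply(gt, c(1, 2), gtToDosage)
  rr <- SummarizedExperiment::rowRanges(vcf)
  GenotypeSet(dose, as.character(seqnames(rr)), start(rr))
}

# count ALT alleles in a GT string such as 0/1 or 1|1; missing calls rejected
gtToDosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|."))
    stop("missing GT call; impute or drop the variant first")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) stop("missing GT call")
  sum(alleles != "0")
}

#' Read / write a probes-by-samples matrix as TSV
#'
#' First column \code{probe_id}, remaining columns one per sample.  Values
#' are written with 15 significant digits so a write/read round trip
#' reproduces them to better than 12 significant digits.
#'
#' @param path file path.
#' @param kind data kind passed to \code{\link{OmicsSet}}.
#' @param annotation,covariates optional, see \code{\link{OmicsSet}}.
#' @return \code{readOmicsMatrix} returns an \linkS4class{OmicsSet}.
#' @export
readOmicsMatrix <- function(path, kind, annotation = NULL, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 1 || colnames(df)[1] != "probe_id")
    stop("matrix TSV must have first column 'probe_id'")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probe ids: ",
         paste(unique(ids[duplicated(ids)])[1:1], collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
                 dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                   ids[i], colnames(df)[j + 1L]))
    }
    vals[, j] <- v
  }
  OmicsSet(vals, kind = kind, annotation = annotation,
           covariates = covariates)
}

#' @rdname readOmicsMatrix
#' @param x an \linkS4class{OmicsSet} (or plain matrix) to write.
#' @export
writeOmicsMatrix <- function(x, path) {
  m <- if (is(x, "SummarizedExperiment")) assay(x, 1) else as.matrix(x)
  df <- data.frame(probe_id = rownames(m),
                   apply(m, 2, function(v) sprintf("%.15g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CpG island intervals from BED
#'
#' BED is 0-based half-open; the returned \link[GenomicRanges]{GRanges} is
#' 1-based closed (the package-wide internal convention).  Intervals are
#' sorted and overlapping or bookended islands merged.
#'
#' @param path BED file (3+ columns).
#' @return A reduced, sorted \code{GRanges}.
#' @export
readCgiBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 3) stop("BED needs at least 3 columns")
  s <- as.numeric(raw[[2]]); e <- as.numeric(raw[[3]])
  if (any(is.na(s)) || any(is.na(e))) stop("non-numeric BED coordinates")
  if (any(e <= s)) {
    i <- which(e <= s)[1]
    stop(sprintf("BED interval with end <= start at line %d", i))
  }
  gr <- rtracklayer::import(path, format = "BED")
  reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
}

#' Read sample covariates (sample_id, age, sex)
#'
#' @param path TSV with header \code{sample_id age sex}; sex coded 0/1.
#' @return data.frame, validated (unique ids, finite non-negative age).
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validateCovariates(df)
}

#' Read probe annotation (probe_id, chrom, pos, gene_symbol)
#'
#' @param path TSV with header.
#' @return validated data.frame.
#' @export
readProbeAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validateAnnotation(df)
}

#' Write a result table as TSV
#'
#' Thin convenience wrapper used by the pipeline stages; tab-separated,
#' no quoting, no row names.
#' @param df data.frame.
#' @param path output path.
#' @export
writeResultTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
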