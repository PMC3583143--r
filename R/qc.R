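#' Methylation beta values from channel intensities
#'
#' beta = M / (M + U), the fraction of methylated signal at a probe.  Zero
#' total intensity has no defined beta and is an error rather than an
#' imputed value.
#'
#' @param methylated,unmethylated nonnegative intensity matrices of equal
#'   shape (probes x samples).
#' @return An \linkS4class{OmicsSet} of kind \code{methylation_beta}.
#' @examples
#' M <- matrix(c(300, 100), 1, 2, dimnames = list("p", c("a", "b")))
#' U <- matrix(c(100, 100), 1, 2, dimnames = list("p", c("a", "b")))
#' assay(computeBeta(M, U))   # 0.75, 0.5
#' @export
computeBeta <- function(methylated, unmethylated) {
  methylated <- as.matrix(methylated); unmethylated <- as.matrix(unmethylated)
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("channel matrices must have the same shape")
  if (min(methylated) < 0 || min(unmethylated) < 0)
    stop("negative intensity")
  tot <- methylated + unmethylated
  if (any(tot == 0)) stop("zero total intensity at some probes; no beta defined")
  beta <- methylated / tot
  dimnames(beta) <- dimnames(methylated)
  OmicsSet(beta, kind = "methylation_beta")
}

#' Quantile normalization across samples
#'
#' Each sample column is replaced by the mean quantile vector so that every
#' column has identical sorted values; tied values share the mean of their
#' quantiles.  Idempotent.  Backed by \code{limma::normalizeQuantiles}.
#'
#' @param m numeric matrix, probes x samples, >= 2 samples.
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need >= 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Detection-p-value filtering of samples then probes
#'
#' Removes samples whose detection p exceeds \code{pCut} in more than
#' \code{probeFrac} of probes, then probes whose detection p exceeds
#' \code{pCut} in more than \code{sampleFrac} of the remaining samples.  The
#' fractions are strict ("more than"): a probe failing in exactly the
#' threshold fraction of samples is retained.
#'
#' @param m data matrix, probes x samples.
#' @param detectionP matrix of detection p-values, same shape as \code{m}.
#' @param probeFrac,sampleFrac,pCut thresholds (defaults 0.01 each).
#' @return list with \code{matrix} (filtered), \code{removedSamples},
#'   \code{removedProbes}.
#' @export
detectionFilter <- function(m, detectionP, probeFrac = 0.01,
                            sampleFrac = 0.01, pCut = 0.01) {
  m <- as.matrix(m); detectionP <- as.matrix(detectionP)
  if (!identical(dim(m), dim(detectionP)))
    stop("detection p matrix must match data shape")
  for (f in c(probeFrac, sampleFrac, pCut))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  fail <- detectionP > pCut
  badSample <- colMeans(fail) > probeFrac
  fail2 <- fail[, !badSample, drop = FALSE]
  badProbe <- rowMeans(fail2) > sampleFrac
  list(matrix = m[!badProbe, !badSample, drop = FALSE],
       removedSamples = colnames(m)[badSample],
       removedProbes = rownames(m)[badProbe])
}

#' Inter-array connectivity outliers (Z.k)
#'
#' For each sample i, k_i is the sum of its Pearson correlations with every
#' other sample; Z.k standardizes k across samples.  Samples with Z.k below
#' the threshold are disconnected from the rest of the cohort and flagged
#' as array outliers.
#'
#' @param m probes x samples matrix, >= 3 samples.
#' @param threshold flag samples with Z.k strictly below this (default -3).
#' @return list with \code{zk} (named numeric) and \code{flagged}
#'   (character sample ids).
#' @export
zkOutliers <- function(m, threshold = -3) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("need >= 3 samples")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant sample vector (undefined correlation): ",
         colnames(m)[which(sds == 0)[1]])
  cc <- cor(m)
  k <- colSums(cc) - 1            # drop self-correlation
  s <- sd(k)
  zk <- if (s == 0) rep(0, length(k)) else (k - mean(k)) / s
  names(zk) <- colnames(m)
  list(zk = zk, flagged = names(zk)[zk < threshold])
}

#' Drop probes whose sequence overlaps a common SNP
#'
#' A probe spans \code{probeSpanBp} bases starting at its annotated
#' position; any probe whose span contains a SNP with MAF above
#' \code{mafCut} is removed, since the polymorphism perturbs hybridization.
#'
#' @param annotation probe annotation data.frame (probe_id, chrom, pos).
#' @param snpPositions data.frame with chrom, pos, maf; NULL keeps all probes
#'   with a warning.
#' @param probeSpanBp probe length in bp (default 50).
#' @param mafCut MAF above which a SNP disqualifies a probe (default 0.01,
#'   strict ">").
#' @return character vector of retained probe ids.
#' @export
dropSnpProbes <- function(annotation, snpPositions = NULL, probeSpanBp = 50,
                          mafCut = 0.01) {
  annotation <- validateAnnotation(annotation)
  if (is.null(snpPositions) || nrow(snpPositions) == 0) {
    warning("no SNP list supplied; all probes retained")
    return(annotation$probe_id)
  }
  snps <- snpPositions[snpPositions$maf > mafCut, , drop = FALSE]
  if (nrow(snps) == 0) return(annotation$probe_id)
  probes <- GRanges(annotation$chrom,
                    IRanges(annotation$pos,
                            annotation$pos + probeSpanBp - 1L))
  snpGr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos))
  hit <- IRanges::overlapsAny(probes, snpGr)
  annotation$probe_id[!hit]
}
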