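# Shared OLS machinery -------------------------------------------------------
#
# All association scans use the same algebra: regress the outcome on one
# predictor of interest plus covariates, and read off the Wald t test of the
# predictor.  By Frisch-Waugh-Lovell this equals the partial-correlation t
# test after residualizing outcome and predictor on [intercept, covariates],
# which lets whole matrices be scanned with one QR decomposition.

# QR of the [intercept, covariates] design for n samples
covariateQr <- function(covariates, n) {
  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && length(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    C <- cbind(C, cm)
  }
  q <- qr(C)
  if (q$rank < ncol(C)) {
    bad <- colnames(C)[q$pivot[(q$rank + 1):ncol(C)]]
    stop("rank-deficient covariate design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  q
}

#' Covariate-adjusted linear association between two vectors
#'
#' Ordinary least squares of \code{y} on \code{x} plus covariates (and an
#' intercept).  Returns the coefficient of \code{x}, its standard error, the
#' two-sided Wald t-test p-value on \code{n - p} degrees of freedom (p =
#' number of model parameters including the intercept), and the adjusted
#' R-squared of the full model.
#'
#' @param y numeric outcome vector.
#' @param x numeric predictor of interest.
#' @param covariates optional data.frame/matrix of additional covariates
#'   (e.g. age and sex), one row per sample.
#' @return list with \code{coefficient}, \code{se}, \code{waldP},
#'   \code{adjustedR2}, \code{df}.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.5 * x + rnorm(50)
#' linearAssociation(y, x)$coefficient
#' @export
linearAssociation <- function(y, x, covariates = NULL) {
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length")
  if (!is.null(covariates) && NROW(covariates) != n)
    stop("covariates must have one row per sample")
  nCov <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n < nCov + 4L) stop("too few samples for the model")
  if (anyNA(y) || anyNA(x)) stop("missing values are not supported")
  q <- covariateQr(covariates, n)
  rx <- qr.resid(q, x)
  if (sum(rx^2) < n * 1e-24 * max(mean(x^2), 1))
    stop("rank-deficient design; offending column: x ",
         "(constant or collinear with covariates)")
  ry <- qr.resid(q, y)
  pModel <- q$rank + 1L
  df <- n - pModel
  sxx <- sum(rx^2)
  beta <- sum(ry * rx) / sxx
  rss <- sum(ry^2) - beta^2 * sxx
  rss <- max(rss, 0)
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  waldP <- 2 * pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adjR2 <- 1 - (1 - r2) * (n - 1) / df
  list(coefficient = beta, se = se, waldP = waldP, adjustedR2 = adjR2,
       df = df)
}

#' Classify a feature pair as cis or trans
#'
#' Cis means same chromosome and point-to-point distance at most
#' \code{window} (boundary inclusive); anything else, including different
#' chromosomes, is trans.  Vectorized.
#'
#' @param chromA,posA,chromB,posB coordinates (1-based bp).
#' @param window cis window in bp (default 500000).
#' @return character vector of "cis"/"trans".
#' @examples
#' classifyCisTrans("chr1", 100000, "chr1", 550000)  # cis (450 kb)
#' classifyCisTrans("chr1", 1, "chr2", 1)            # trans
#' @export
classifyCisTrans <- function(chromA, posA, chromB, posB, window = 500000) {
  ifelse(as.character(chromA) == as.character(chromB) &
           abs(as.numeric(posA) - as.numeric(posB)) <= window,
         "cis", "trans")
}

# enumerate (i, j) index pairs with same chromosome and |posA - posB| <= window
cisPairsIdx <- function(chromA, posA, chromB, posB, window) {
  a <- GRanges(chromA, IRanges(pmax(1, posA - window), posA + window))
  b <- GRanges(chromB, IRanges(posB, posB))
  hits <- GenomicRanges::findOverlaps(a, b)
  cbind(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
}

# residualize the samples x probes transpose of an assay on the covariate QR,
# returning samples x probes residual matrix
residualMatrix <- function(m, q) {
  r <- qr.resid(q, t(m))
  colnames(r) <- rownames(m)
  r
}

# association stats for selected (i, j) pairs given residual matrices
# RY (samples x outcomes), RX (samples x predictors); yTss = centered total
# sum of squares of the raw outcomes
pairStats <- function(RY, RX, pairsIJ, df, n, yTss) {
  iY <- pairsIJ[, "j"]; iX <- pairsIJ[, "i"]   # i indexes X-side, j Y-side
  sxx <- colSums(RX^2)[iX]
  syy <- colSums(RY^2)[iY]
  sxy <- colSums(RX[, iX, drop = FALSE] * RY[, iY, drop = FALSE])
  beta <- sxy / sxx
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  waldP <- 2 * pt(-abs(tval), df)
  r2 <- 1 - rss / yTss[iY]
  adjR2 <- 1 - (1 - r2) * (n - 1) / df
  data.frame(coefficient = beta, se = se, waldP = waldP, adjustedR2 = adjR2)
}

#' Scan methylation-expression associations with cis/trans split correction
#'
#' Regresses each expression probe (outcome) on each methylation probe
#' (predictor) with age and sex as covariates.  Pairs within the cis window
#' are corrected by Benjamini-Hochberg FDR pooled over all enumerated cis
#' tests (significant at \code{q <= fdrQ}); all remaining pairs are trans
#' and corrected by Bonferroni with the full probe product, significant at
#' \code{p <= alpha / (n_meth * n_expr)}.  Significant records are labeled
#' positive or negative by the sign of the coefficient: a negative
#' association means higher methylation goes with lower expression.
#'
#' @param meth,expr annotated \linkS4class{OmicsSet}s sharing samples.
#' @param covariates data.frame with sample_id, age, sex; defines the sample
#'   order all matrices are aligned to.  NULL uses the colData of
#'   \code{meth}, or no covariates if absent.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return list with \code{records} (cis tests plus significant trans tests;
#'   columns meth_probe, expr_probe, relation, coefficient, se, wald_p,
#'   adjusted, significant, sign, adjusted_r2), and \code{summary} (counts by
#'   relation and sign among significant records, plus unique probe counts).
#' @export
scanMethExpr <- function(meth, expr, covariates = NULL,
                         config = analysisConfig()) {
  al <- alignLayers(meth, expr, covariates = covariates)
  M <- assay(al$a, "values"); E <- assay(al$b, "values")
  n <- ncol(M)
  q <- covariateQr(al$covariates, n)
  RM <- residualMatrix(M, q)
  RE <- residualMatrix(E, q)
  df <- n - (q$rank + 1L)
  eTss <- apply(E, 1, function(v) sum((v - mean(v))^2))
  annM <- probeAnnotation(al$a); annE <- probeAnnotation(al$b)

  cis <- cisPairsIdx(annM$chrom, annM$pos, annE$chrom, annE$pos,
                     config@cisWindowBp)
  nTestsTrans <- as.numeric(nrow(M)) * nrow(E)
  bonf <- config@alpha / nTestsTrans

  records <- NULL
  if (nrow(cis) > 0) {
    st <- pairStats(RE, RM, cis, df, n, eTss)
    qv <- p.adjust(st$waldP, method = "BH")
    records <- data.frame(
      meth_probe = rownames(M)[cis[, "i"]],
      expr_probe = rownames(E)[cis[, "j"]],
      relation = "cis", st[, c("coefficient", "se")],
      wald_p = st$waldP, adjusted = qv,
      significant = qv <= config@fdrQ,
      adjusted_r2 = st$adjustedR2, stringsAsFactors = FALSE)
  } else {
    warning("zero cis pairs enumerated")
  }

  # trans: everything not cis; significant pairs found by thresholding the
  # full residual cross-correlation, avoiding materializing all pairs
  R <- crossprod(RE, RM) /
    tcrossprod(sqrt(colSums(RE^2)), sqrt(colSums(RM^2)))
  R[R > 1] <- 1; R[R < -1] <- -1
  tcrit <- abs(qt(bonf / 2, df))
  rcrit <- tcrit / sqrt(df + tcrit^2)
  hitIdx <- which(abs(R) >= rcrit, arr.ind = TRUE)  # rows: (expr, meth)
  if (nrow(hitIdx) > 0) {
    tp <- cbind(i = hitIdx[, 2], j = hitIdx[, 1])
    rel <- classifyCisTrans(annM$chrom[tp[, "i"]], annM$pos[tp[, "i"]],
                            annE$chrom[tp[, "j"]], annE$pos[tp[, "j"]],
                            config@cisWindowBp)
    tp <- tp[rel == "trans", , drop = FALSE]
    if (nrow(tp) > 0) {
      if (is.finite(config@transMaxPairs) &&
          nrow(tp) > config@transMaxPairs) {
        set.seed(config@seed)
        tp <- tp[sort(sample.int(nrow(tp), config@transMaxPairs)), ,
                 drop = FALSE]
      }
      st <- pairStats(RE, RM, tp, df, n, eTss)
      padj <- pmin(st$waldP * nTestsTrans, 1)
      rec <- data.frame(
        meth_probe = rownames(M)[tp[, "i"]],
        expr_probe = rownames(E)[tp[, "j"]],
        relation = "trans", st[, c("coefficient", "se")],
        wald_p = st$waldP, adjusted = padj,
        significant = st$waldP <= bonf,
        adjusted_r2 = st$adjustedR2, stringsAsFactors = FALSE)
      rec <- rec[rec$significant, , drop = FALSE]
      records <- rbind(records, rec)
    }
  }
  if (is.null(records))
    records <- data.frame(meth_probe = character(), expr_probe = character(),
                          relation = character(), coefficient = numeric(),
                          se = numeric(), wald_p = numeric(),
                          adjusted = numeric(), significant = logical(),
                          adjusted_r2 = numeric())
  records$sign <- ifelse(records$coefficient > 0, "positive", "negative")
  rownames(records) <- NULL
  list(records = records, summary = assocSummary(records))
}

assocSummary <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  cnt <- function(rel, sgn)
    sum(sig$relation == rel & sig$sign == sgn)
  uni <- function(rel, col) length(unique(sig[[col]][sig$relation == rel]))
  data.frame(
    relation = c("cis", "trans"),
    positive = c(cnt("cis", "positive"), cnt("trans", "positive")),
    negative = c(cnt("cis", "negative"), cnt("trans", "negative")),
    meth_probes = c(uni("cis", "meth_probe"), uni("trans", "meth_probe")),
    expr_probes = c(uni("cis", "expr_probe"), uni("trans", "expr_probe")))
}

# align two OmicsSets (and optional covariates) to a common sample order;
# covariate file order wins when supplied
alignLayers <- function(a, b, covariates = NULL) {
  if (is.null(covariates)) {
    cd <- colData(a)
    if (all(c("age", "sex") %in% colnames(cd)))
      covariates <- data.frame(sample_id = rownames(cd), age = cd$age,
                               sex = cd$sex, stringsAsFactors = FALSE)
  } else {
    covariates <- validateCovariates(as.data.frame(covariates))
  }
  shared <- intersect(colnames(a), colnames(b))
  if (!is.null(covariates)) shared <- intersect(covariates$sample_id, shared)
  if (length(shared) < 4) stop("too few shared samples across layers")
  ord <- if (!is.null(covariates))
    covariates$sample_id[covariates$sample_id %in% shared] else shared
  covOut <- NULL
  if (!is.null(covariates)) {
    idx <- match(ord, covariates$sample_id)
    covOut <- data.frame(age = covariates$age[idx], sex = covariates$sex[idx])
  }
  list(a = a[, ord], b = b[, ord], covariates = covOut, samples = ord)
}
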