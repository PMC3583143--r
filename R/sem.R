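# Five-model causal analysis of (SNP, methylation, expression) triples.
#
# Each candidate triple is scored by fitting five structural equation models
# by maximum likelihood on the 3x3 sample covariance of (S, M, E):
#   M1: S -> M -> E     M2: S -> E -> M     M3: M <- S -> E
#   M4: S -> E <- M     M5: S -> M <- E
# Every model has 5 free parameters (exogenous variances, two path
# coefficients, residual variances) against 6 observed moments, so each has
# one degree of freedom; the single testable constraint is a vanishing
# partial or marginal correlation (e.g. M1: S independent of E given M).
# Large model-fit p-values mean good fit.

semModelIds <- c("M1", "M2", "M3", "M4", "M5")

# model-implied covariance; th = (log v1, a, log v2, b, log v3) with the
# variance parameters model-specific (see semInit)
semImplied <- function(modelId, th) {
  v1 <- exp(th[1]); a <- th[2]; v2 <- exp(th[3]); b <- th[4]; v3 <- exp(th[5])
  S <- matrix(0, 3, 3)
  switch(modelId,
    M1 = { # v1=var(S), v2=resid var(M), v3=resid var(E)
      S[1, 1] <- v1; S[1, 2] <- a * v1
      S[2, 2] <- a^2 * v1 + v2
      S[1, 3] <- a * b * v1; S[2, 3] <- b * S[2, 2]
      S[3, 3] <- b^2 * S[2, 2] + v3
    },
    M2 = { # v1=var(S), v2=resid var(E), v3=resid var(M)
      S[1, 1] <- v1; S[1, 3] <- a * v1
      S[3, 3] <- a^2 * v1 + v2
      S[1, 2] <- a * b * v1; S[2, 3] <- b * S[3, 3]
      S[2, 2] <- b^2 * S[3, 3] + v3
    },
    M3 = { # common cause: v2=resid var(M), v3=resid var(E)
      S[1, 1] <- v1
      S[1, 2] <- a * v1; S[1, 3] <- b * v1
      S[2, 2] <- a^2 * v1 + v2; S[3, 3] <- b^2 * v1 + v3
      S[2, 3] <- a * b * v1
    },
    M4 = { # collider at E: v2=var(M), v3=resid var(E); cov(S,M)=0
      S[1, 1] <- v1; S[2, 2] <- v2
      S[1, 3] <- a * v1; S[2, 3] <- b * v2
      S[3, 3] <- a^2 * v1 + b^2 * v2 + v3
    },
    M5 = { # collider at M: v2=var(E), v3=resid var(M); cov(S,E)=0
      S[1, 1] <- v1; S[3, 3] <- v2
      S[1, 2] <- a * v1; S[2, 3] <- b * v2
      S[2, 2] <- a^2 * v1 + b^2 * v2 + v3
    },
    stop("unknown model id: ", modelId))
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

# analytic moment-matching start values
semInit <- function(modelId, S) {
  s11 <- S[1, 1]; s22 <- S[2, 2]; s33 <- S[3, 3]
  s12 <- S[1, 2]; s13 <- S[1, 3]; s23 <- S[2, 3]
  pos <- function(x, ref) max(x, 1e-4 * ref)
  switch(modelId,
    M1 = c(log(s11), s12 / s11, log(pos(s22 - s12^2 / s11, s22)),
           s23 / s22, log(pos(s33 - s23^2 / s22, s33))),
    M2 = c(log(s11), s13 / s11, log(pos(s33 - s13^2 / s11, s33)),
           s23 / s33, log(pos(s22 - s23^2 / s33, s22))),
    M3 = c(log(s11), s12 / s11, log(pos(s22 - s12^2 / s11, s22)),
           s13 / s11, log(pos(s33 - s13^2 / s11, s33))),
    M4 = c(log(s11), s13 / s11, log(s22),
           s23 / s22, log(pos(s33 - s13^2 / s11 - s23^2 / s22, s33))),
    M5 = c(log(s11), s12 / s11, log(s33),
           s23 / s33, log(pos(s22 - s12^2 / s11 - s23^2 / s33, s22))))
}

semDiscrepancy <- function(modelId, th, S, logDetS) {
  Sig <- semImplied(modelId, th)
  dt <- determinant(Sig, logarithm = TRUE)
  if (dt$sign <= 0) return(1e10)
  inv <- tryCatch(solve(Sig), error = function(e) NULL)
  if (is.null(inv)) return(1e10)
  as.numeric(dt$modulus) + sum(inv * S) - logDetS - 3
}

#' Fit one causal model to a 3x3 covariance by maximum likelihood
#'
#' Minimizes the ML discrepancy F(theta) = ln|Sigma(theta)| +
#' tr(S Sigma(theta)^-1) - ln|S| - 3 over the model's five parameters
#' (variances on the log scale), with an analytic moment-matching start plus
#' jittered restarts.  The model-fit statistic is chisq = (n - 1) F_min on
#' one degree of freedom; a large p indicates the constraint the model
#' imposes is compatible with the data.
#'
#' @param modelId one of "M1".."M5" (variable order S, M, E).
#' @param sampleCov symmetric positive-definite 3x3 covariance.
#' @param n sample size (> 6).
#' @param nStarts optimization restarts (default 5).
#' @param multiplier "nm1" for the classical (n - 1) chi-square multiplier,
#'   or "n".
#' @return list with modelId, fmin, chisq, df, p, estimates (named vector:
#'   v1, a, v2, b, v3), converged.
#' @examples
#' S <- matrix(c(1, .5, .3, .5, 1, .6, .3, .6, 1), 3)
#' semFit("M1", S, n = 100)$p
#' @export
semFit <- function(modelId, sampleCov, n, nStarts = 5,
                   multiplier = c("nm1", "n")) {
  multiplier <- match.arg(multiplier)
  modelId <- match.arg(modelId, semModelIds)
  S <- as.matrix(sampleCov)
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("sampleCov must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sampleCov must be positive definite")
  if (n <= 6) stop("n must exceed 6")
  logDetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  obj <- function(th) semDiscrepancy(modelId, th, S, logDetS)
  th0 <- semInit(modelId, S)
  best <- NULL
  set0 <- list(th0)
  if (nStarts > 1)
    for (k in seq_len(nStarts - 1))
      set0[[k + 1]] <- th0 + (k / nStarts) * c(0.3, 0.5, 0.3, 0.5, 0.3) *
        sin(k * (1:5) * 2.399)   # deterministic jitter
  for (start in set0) {
    o <- tryCatch(
      optim(start, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) next
    o2 <- optim(o$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    cand <- if (o2$value < o$value) o2 else o
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best))
    return(list(modelId = modelId, fmin = NA_real_, chisq = NA_real_,
                df = 1L, p = NA_real_, estimates = NULL, converged = FALSE))
  # converged when a numerical gradient check finds no further descent
  gr <- numericGradient(obj, best$par)
  converged <- is.finite(best$value) && best$value < 1e9 &&
    sqrt(sum(gr^2)) < 1e-4 * (1 + abs(best$value))
  fmin <- max(best$value, 0)
  mult <- if (multiplier == "nm1") n - 1 else n
  chisq <- mult * fmin
  est <- c(v1 = exp(best$par[1]), a = best$par[2], v2 = exp(best$par[3]),
           b = best$par[4], v3 = exp(best$par[5]))
  list(modelId = modelId, fmin = fmin, chisq = chisq, df = 1L,
       p = pchisq(chisq, df = 1, lower.tail = FALSE), estimates = est,
       converged = converged)
}

numericGradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' LEO scores from a vector of five model-fit p-values
#'
#' The local-edge-orienting score of a focal model is the base-10 logarithm
#' of its model-fit p-value divided by the best (largest) p-value among the
#' competing models.  A positive score means the focal model fits better
#' than every competitor.
#'
#' @param p numeric vector of 5 model-fit p-values (order M1..M5).
#' @param focal index of the focal model (1 or 2 in practice).
#' @param competing indices of competing models (default: all others).
#' @return numeric LEO score.
#' @examples
#' leoScoreFromP(c(0.5, 1e-4, 1e-4, 1e-4, 1e-4), focal = 1)  # ~3.699
#' @export
leoScoreFromP <- function(p, focal, competing = setdiff(seq_along(p), focal)) {
  log10(p[focal] / max(p[competing]))
}

#' Residualize probe levels on covariates
#'
#' OLS residuals of each probe (row) on \[intercept, covariates\]; used to
#' protect the causal analysis from age and sex effects.  Residuals have
#' mean zero and are orthogonal to every covariate column.
#'
#' @param levels probes x samples matrix (or \linkS4class{OmicsSet}).
#' @param covariates data.frame of covariates, one row per sample.
#' @return matrix of residuals, same shape and dimnames as the input values.
#' @export
residualize <- function(levels, covariates) {
  m <- if (is(levels, "SummarizedExperiment")) assay(levels, 1) else
    as.matrix(levels)
  if (anyNA(m)) stop("missing values are not supported")
  q <- covariateQr(covariates, ncol(m))
  r <- t(qr.resid(q, t(m)))
  dimnames(r) <- dimnames(m)
  r
}

#' Single-marker LEO analysis of one (SNP, methylation, expression) triple
#'
#' Fits the five causal models on the joint covariance of the raw SNP dosage
#' (the causal anchor; genotypes are fixed at each locus) and the
#' age/sex-residualized methylation and expression levels, and computes the
#' LEO scores for the two focal directions: \code{leo_m1} supports
#' S -> M -> E, \code{leo_m2} supports S -> E -> M, each against all
#' competing models (restrictable via \code{competing}).
#'
#' @param s SNP dosage vector.
#' @param m,e residualized methylation / expression vectors.
#' @param leoThreshold score above which a direction is called supported
#'   (default 0.8).
#' @param competing "all" (default) or "focal" to restrict each score's
#'   denominator to the two focal models only.
#' @param multiplier chi-square multiplier, see \code{\link{semFit}}.
#' @return list with p (named vector M1..M5), leo_m1, leo_m2, bestModel,
#'   focalFitP (fit p of the better-scoring focal model), passM1, passM2,
#'   converged.
#' @export
leoSingleMarker <- function(s, m, e, leoThreshold = 0.8,
                            competing = c("all", "focal"),
                            multiplier = "nm1") {
  competing <- match.arg(competing)
  n <- length(s)
  if (length(m) != n || length(e) != n) stop("vectors must share length")
  if (anyNA(s) || anyNA(m) || anyNA(e)) stop("complete vectors required")
  S <- cov(cbind(S = s, M = m, E = e))
  fits <- lapply(semModelIds, semFit, sampleCov = S, n = n,
                 multiplier = multiplier)
  p <- vapply(fits, `[[`, numeric(1), "p")
  names(p) <- semModelIds
  conv <- all(vapply(fits, `[[`, logical(1), "converged"))
  if (!conv || anyNA(p))
    return(list(p = p, leo_m1 = NA_real_, leo_m2 = NA_real_,
                bestModel = NA_character_, focalFitP = NA_real_,
                passM1 = NA, passM2 = NA, converged = FALSE))
  comp1 <- if (competing == "all") 2:5 else 2L
  comp2 <- if (competing == "all") c(1L, 3:5) else 1L
  leo1 <- unname(leoScoreFromP(p, 1L, comp1))
  leo2 <- unname(leoScoreFromP(p, 2L, comp2))
  best <- semModelIds[which.max(p)]
  focal <- if (leo1 >= leo2) 1L else 2L
  list(p = p, leo_m1 = leo1, leo_m2 = leo2, bestModel = best,
       focalFitP = unname(p[focal]),
       passM1 = leo1 > leoThreshold, passM2 = leo2 > leoThreshold,
       converged = TRUE)
}

#' Screen candidate triples and score them with LEO
#'
#' Builds (SNP, methylation probe, expression probe) triples from the
#' significant cis methylation-expression pairs whose two members are both
#' significantly associated with the same SNP in cis, then runs
#' \code{\link{leoSingleMarker}} on each triple using age/sex-residualized
#' levels and raw dosages.
#'
#' @param assocRecords records from \code{\link{scanMethExpr}}.
#' @param qtlMeth,qtlExpr records from \code{\link{scanQtl}} run on the
#'   methylation and expression layers.
#' @param genotypes \linkS4class{GenotypeSet}.
#' @param meth,expr \linkS4class{OmicsSet}s.
#' @param covariates data.frame with sample_id, age, sex.
#' @param config \linkS4class{AnalysisConfig}.
#' @param topMeth keep only this many methylation probes, ranked by best cis
#'   association p (default Inf = all).
#' @return list with \code{triples} (one row per triple: snp_id, meth_probe,
#'   expr_probe, p1..p5, leo_m1, leo_m2, best_model, focal_fit_p, pass
#'   flags, converged; sorted by leo_m1 descending) and \code{summary}
#'   (counts passing the threshold per focal model).
#' @export
screenTriples <- function(assocRecords, qtlMeth, qtlExpr, genotypes, meth,
                          expr, covariates = NULL,
                          config = analysisConfig(), topMeth = Inf) {
  sigPairs <- assocRecords[assocRecords$significant &
                             assocRecords$relation == "cis", , drop = FALSE]
  if (is.finite(topMeth) && nrow(sigPairs) > 0) {
    bestP <- aggregate(wald_p ~ meth_probe, data = sigPairs, FUN = min)
    keepProbes <- bestP$meth_probe[order(bestP$wald_p)][
      seq_len(min(topMeth, nrow(bestP)))]
    sigPairs <- sigPairs[sigPairs$meth_probe %in% keepProbes, , drop = FALSE]
  }
  sm <- qtlMeth[qtlMeth$passes_threshold & qtlMeth$relation == "cis", ,
                drop = FALSE]
  se_ <- qtlExpr[qtlExpr$passes_threshold & qtlExpr$relation == "cis", ,
                 drop = FALSE]
  emptyOut <- list(
    triples = data.frame(snp_id = character(), meth_probe = character(),
                         expr_probe = character()),
    summary = data.frame(model = c("M1", "M2"), n_pass = c(0L, 0L)))
  if (nrow(sigPairs) == 0 || nrow(sm) == 0 || nrow(se_) == 0)
    return(emptyOut)
  # enumerate candidate triples before touching the data matrices: a pair
  # qualifies only with a SNP significantly cis-associated with both members
  cand <- list()
  for (k in seq_len(nrow(sigPairs))) {
    mp <- sigPairs$meth_probe[k]; ep <- sigPairs$expr_probe[k]
    snps <- intersect(sm$snp_id[sm$target_probe == mp],
                      se_$snp_id[se_$target_probe == ep])
    if (length(snps))
      cand[[length(cand) + 1L]] <- data.frame(snp_id = snps, meth_probe = mp,
                                              expr_probe = ep,
                                              stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(emptyOut)
  cand <- do.call(rbind, cand)

  al <- alignLayers(meth, expr, covariates = covariates)
  geno <- genotypes[, al$samples]
  RM <- residualize(al$a, al$covariates)
  RE <- residualize(al$b, al$covariates)
  G <- assay(geno, "dosage")

  rows <- list()
  for (k in seq_len(nrow(cand))) {
    sid <- cand$snp_id[k]; mp <- cand$meth_probe[k]; ep <- cand$expr_probe[k]
    leo <- leoSingleMarker(G[sid, ], RM[mp, ], RE[ep, ],
                           leoThreshold = config@leoThreshold)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sid, meth_probe = mp, expr_probe = ep,
      p1 = leo$p[1], p2 = leo$p[2], p3 = leo$p[3], p4 = leo$p[4],
      p5 = leo$p[5], leo_m1 = leo$leo_m1, leo_m2 = leo$leo_m2,
      best_model = leo$bestModel, focal_fit_p = leo$focalFitP,
      pass_m1 = leo$passM1, pass_m2 = leo$passM2,
      converged = leo$converged, stringsAsFactors = FALSE)
  }
  triples <- do.call(rbind, rows)
  rownames(triples) <- NULL
  triples <- triples[order(-triples$leo_m1), , drop = FALSE]
  summary <- data.frame(
    model = c("M1", "M2"),
    n_pass = c(sum(triples$pass_m1, na.rm = TRUE),
               sum(triples$pass_m2, na.rm = TRUE)))
  list(triples = triples, summary = summary)
}
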