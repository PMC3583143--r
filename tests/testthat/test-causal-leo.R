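test_that("residualization gives mean-zero residuals orthogonal to covariates", {
  set.seed(61)
  n <- 80
  covar <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  m <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:n)))
  r <- residualize(m, covar)
  expect_equal(dim(r), dim(m))
  expect_lt(max(abs(rowMeans(r))), 1e-10)
  expect_lt(max(abs(r %*% covar$age)), 1e-8)
  expect_lt(max(abs(r %*% covar$sex)), 1e-8)

  # a level that is exactly 2 * age residualizes to zero
  m2 <- matrix(2 * covar$age, 1, n, dimnames = list("p", paste0("s", 1:n)))
  expect_lt(max(abs(residualize(m2, covar))), 1e-10)

  # orthogonal covariate: residuals equal the centered level
  covOrth <- data.frame(z = rep(c(-1, 1), n / 2))
  lev <- matrix(rep(c(5, 5, 9, 9), n / 4), 1, n,
                dimnames = list("p", paste0("s", 1:n)))
  expect_equal(unname(residualize(lev, covOrth)[1, ]),
               unname(lev[1, ] - mean(lev[1, ])), tolerance = 1e-10)
})

test_that("a covariance satisfying a model's constraint fits it perfectly", {
  set.seed(62)
  # build S with cov(S,E) = cov(S,M) cov(M,E) / var(M): S independent of E
  # given M, the M1 constraint
  S <- randPD3()
  S[1, 3] <- S[3, 1] <- S[1, 2] * S[2, 3] / S[2, 2]
  fit <- semFit("M1", S, n = 500)
  expect_lte(fit$chisq, 1e-6)
  expect_gt(fit$p, 0.999)
  expect_true(fit$converged)
})

test_that("each model reproduces its own implied covariance (self-consistency)", {
  for (mid in c("M1", "M2", "M3", "M4", "M5")) {
    S <- oracleImpliedCov(mid, 0.7, 0.5)
    fit <- semFit(mid, S, n = 1000)
    expect_lte(fit$chisq, 1e-6, label = mid)
  }
})

test_that("numerical ML chi-square matches the closed-form constraint statistic", {
  set.seed(63)
  for (rep in 1:20) {
    S <- randPD3()
    for (mid in c("M1", "M3", "M4")) {
      fit <- semFit(mid, S, n = 200)
      oracle <- semOracleChisq(mid, S, 200)
      expect_lt(abs(fit$chisq - oracle) / max(oracle, 1e-8), 0.01,
                label = paste(mid, "rep", rep))
    }
  }
  expect_error(semFit("M1", diag(c(1, -1, 1)), 100), "positive definite")
  expect_error(semFit("M1", randPD3(), 5), "n must exceed 6")
})

test_that("LEO scores follow their log-ratio definition", {
  p <- c(0.5, 1e-4, 1e-4, 1e-4, 1e-4)
  expect_equal(leoScoreFromP(p, 1), log10(0.5 / 1e-4), tolerance = 1e-12)
  set.seed(64)
  for (rep in 1:50) {
    p <- runif(5)
    expect_equal(leoScoreFromP(p, 1) > 0, p[1] > max(p[-1]))
    expect_equal(leoScoreFromP(p, 2) > 0, p[2] > max(p[-2]))
    # both focal scores cannot be positive simultaneously
    expect_false(leoScoreFromP(p, 1) > 0 && leoScoreFromP(p, 2) > 0)
  }
})

test_that("swapping methylation and expression exchanges the focal scores", {
  tri <- simulateCausalTriple("M1", 500, 0.3, 0.6, 0.6, seed = 65)
  fwd <- leoSingleMarker(tri$s, tri$m, tri$e)
  rev <- leoSingleMarker(tri$s, tri$e, tri$m)
  expect_equal(fwd$leo_m1, rev$leo_m2, tolerance = 1e-4)
  expect_equal(fwd$leo_m2, rev$leo_m1, tolerance = 1e-4)
})

test_that("model fit is invariant to positive rescaling of the levels", {
  tri <- simulateCausalTriple("M1", 300, 0.3, 0.5, 0.4, seed = 66)
  base <- leoSingleMarker(tri$s, tri$m, tri$e)
  scaled <- leoSingleMarker(tri$s, 7.3 * tri$m, 0.2 * tri$e)
  expect_equal(base$p, scaled$p, tolerance = 1e-5)
  expect_equal(base$leo_m1, scaled$leo_m1, tolerance = 1e-3)
})

test_that("triples need a SNP shared by both members of a pair", {
  assoc <- data.frame(meth_probe = "cg1", expr_probe = "ex1",
                      relation = "cis", wald_p = 1e-8, significant = TRUE)
  qm <- data.frame(snp_id = "snpA", target_probe = "cg1", relation = "cis",
                   passes_threshold = TRUE)
  qe <- data.frame(snp_id = "snpB", target_probe = "ex1", relation = "cis",
                   passes_threshold = TRUE)
  out <- screenTriples(assoc, qm, qe, genotypes = NULL, meth = NULL,
                       expr = NULL)
  expect_equal(nrow(out$triples), 0)
  expect_equal(out$summary$n_pass, c(0L, 0L))
})

test_that("screening scores planted triples from cohort-style objects", {
  set.seed(67)
  n <- 148
  samples <- paste0("s", seq_len(n))
  covar <- data.frame(sample_id = samples, age = runif(n, 20, 80),
                      sex = rep(c(0, 1), length.out = n))
  tri <- simulateCausalTriple("M1", n, 0.3, 0.7, 0.7)
  dos <- matrix(tri$s, 1, n, dimnames = list("snpA", samples))
  geno <- GenotypeSet(dos, "chr1", 200000L)
  mScaled <- (tri$m - min(tri$m)) / (diff(range(tri$m)) + 0.01)  # linear map
  mm <- matrix(mScaled, 1, n, dimnames = list("cg1", samples))
  ee <- matrix(tri$e + 8, 1, n, dimnames = list("ex1", samples))
  annM <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 150000,
                     gene_symbol = "G1")
  annE <- data.frame(probe_id = "ex1", chrom = "chr1", pos = 250000,
                     gene_symbol = "G1")
  meth <- OmicsSet(mm, "methylation_beta", annM, covar)
  expr <- OmicsSet(ee, "expression_log2", annE, covar)
  assoc <- scanMethExpr(meth, expr, covar)
  qm <- scanQtl(meth, geno, covar)
  qe <- scanQtl(expr, geno, covar)
  out <- screenTriples(assoc$records, qm$records, qe$records, geno, meth,
                       expr, covar)
  expect_equal(nrow(out$triples), 1)
  expect_equal(out$triples$best_model, "M1")
  expect_true(out$triples$pass_m1)
})
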