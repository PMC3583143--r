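test_that("exact and orthogonal fits give the textbook answers", {
  x <- c(1:10)
  fit <- linearAssociation(2 * x, x)
  expect_equal(fit$coefficient, 2, tolerance = 1e-12)
  expect_lt(fit$waldP, 1e-12)
  expect_equal(fit$adjustedR2, 1, tolerance = 1e-12)

  # orthogonal by construction: coefficient numerically zero
  x2 <- rep(c(-1, 1), 5)
  y2 <- rep(c(1, 1, -1, -1), length.out = 10)   # sum(x2 * y2) = 0
  fit2 <- linearAssociation(y2, x2)
  expect_equal(fit2$coefficient, 0, tolerance = 1e-14)

  expect_error(linearAssociation(rnorm(10), rep(1, 10)), "x")
})

test_that("association statistics match an independent lm() oracle", {
  set.seed(17)
  n <- 5000
  covar <- data.frame(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  x <- rnorm(n)
  y <- 0.5 * x + 0.01 * covar$age + 0.3 * covar$sex + rnorm(n)
  fit <- linearAssociation(y, x, covar)
  ref <- summary(lm(y ~ x + age + sex, data = covar))
  expect_equal(fit$coefficient, ref$coefficients["x", 1], tolerance = 1e-10)
  expect_equal(fit$se, ref$coefficients["x", 2], tolerance = 1e-10)
  expect_equal(fit$waldP, ref$coefficients["x", 4], tolerance = 1e-10)
  expect_equal(fit$adjustedR2, ref$adj.r.squared, tolerance = 1e-10)
  expect_lt(abs(fit$coefficient - 0.5), 4 * fit$se)
})

test_that("Wald p equals the partial-correlation t test", {
  set.seed(18)
  for (rep in 1:10) {
    n <- 60
    covar <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
    x <- rnorm(n); y <- 0.2 * x + rnorm(n)
    fit <- linearAssociation(y, x, covar)
    C <- cbind(1, as.matrix(covar))
    rx <- residuals(lm.fit(C, x)); ry <- residuals(lm.fit(C, y))
    r <- cor(rx, ry)
    df <- n - 4
    tstat <- r * sqrt(df) / sqrt(1 - r^2)
    expect_equal(fit$waldP, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  }
})

test_that("sign is invariant to positive rescaling and flipped by negation", {
  set.seed(19)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50)
  base <- linearAssociation(y, x)
  scaled <- linearAssociation(3.7 * y, 0.2 * x)
  neg <- linearAssociation(y, -x)
  expect_equal(sign(base$coefficient), sign(scaled$coefficient))
  expect_equal(sign(base$coefficient), -sign(neg$coefficient))
  expect_equal(base$waldP, scaled$waldP, tolerance = 1e-12)
  expect_equal(base$waldP, neg$waldP, tolerance = 1e-12)
})

test_that("cis/trans classification uses an inclusive same-chromosome window", {
  expect_equal(classifyCisTrans("chr1", 100000, "chr1", 550000), "cis")
  expect_equal(classifyCisTrans("chr1", 100000, "chr2", 100000), "trans")
  expect_equal(classifyCisTrans("chr1", 1, "chr1", 500001), "cis")
  expect_equal(classifyCisTrans("chr1", 1, "chr1", 500002), "trans")
})

makeScanFixture <- function(n = 80, nM = 12, nE = 12, seed = 23,
                            plant = NULL) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  covar <- data.frame(sample_id = samples, age = runif(n, 20, 80),
                      sex = rep(c(0, 1), length.out = n))
  mm <- matrix(runif(nM * n, 0.2, 0.8), nM, n,
               dimnames = list(paste0("cg", seq_len(nM)), samples))
  ee <- matrix(rnorm(nE * n, 8), nE, n,
               dimnames = list(paste0("ex", seq_len(nE)), samples))
  if (!is.null(plant))
    ee[plant$e, ] <- plant$rho * scale(mm[plant$m, ])[, 1] +
      sqrt(1 - plant$rho^2) * rnorm(n) + 8
  annM <- data.frame(probe_id = rownames(mm), chrom = "chr1",
                     pos = seq(1e5, by = 1e5, length.out = nM),
                     gene_symbol = NA)
  annE <- data.frame(probe_id = rownames(ee), chrom = "chr1",
                     pos = seq(1e5, by = 1e5, length.out = nE) + 1e4,
                     gene_symbol = NA)
  list(meth = OmicsSet(mm, "methylation_beta", annM, covar),
       expr = OmicsSet(ee, "expression_log2", annE, covar),
       covar = covar)
}

test_that("scan enumerates cis pairs by coordinates and pools BH over them", {
  fx <- makeScanFixture()
  res <- scanMethExpr(fx$meth, fx$expr, fx$covar)
  cis <- res$records[res$records$relation == "cis", ]
  expect_gt(nrow(cis), 0)
  ann <- probeAnnotation(fx$meth); annE <- probeAnnotation(fx$expr)
  for (k in seq_len(nrow(cis))) {
    pm <- ann$pos[ann$probe_id == cis$meth_probe[k]]
    pe <- annE$pos[annE$probe_id == cis$expr_probe[k]]
    expect_lte(abs(pm - pe), 500000)
  }
  # BH adjusted values equal the brute-force step-up on the same p-vector
  expect_equal(cis$adjusted, oracleBH(cis$wald_p), tolerance = 1e-12)
  expect_setequal(which(cis$significant), which(oracleBH(cis$wald_p) <= 0.05))
})

test_that("a planted negative cis pair is recovered with the right sign", {
  hits <- vapply(1:20, function(s) {
    fx <- makeScanFixture(n = 148, seed = 100 + s,
                          plant = list(m = "cg3", e = "ex3", rho = -sqrt(0.3)))
    res <- scanMethExpr(fx$meth, fx$expr, fx$covar)
    rec <- res$records
    hit <- rec[rec$meth_probe == "cg3" & rec$expr_probe == "ex3", ]
    nrow(hit) == 1 && hit$significant && hit$sign == "negative"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("trans records obey the probe-product Bonferroni threshold", {
  fx <- makeScanFixture(n = 120, seed = 55)
  # plant a strong cross-chromosome association
  mm <- assay(fx$meth); ee <- assay(fx$expr)
  ee["ex9", ] <- -4 * scale(mm["cg2", ])[, 1] + 8 + rnorm(120, 0, 0.3)
  annE <- probeAnnotation(fx$expr); annE$chrom[annE$probe_id == "ex9"] <- "chr2"
  expr2 <- OmicsSet(ee, "expression_log2", annE, fx$covar)
  res <- scanMethExpr(fx$meth, expr2, fx$covar)
  tr <- res$records[res$records$relation == "trans", ]
  expect_true(all(tr$significant))
  expect_true(all(tr$wald_p <= 0.05 / (12 * 12)))
  expect_true(any(tr$meth_probe == "cg2" & tr$expr_probe == "ex9"))
})

test_that("summary counts significant records by relation and sign", {
  fx <- makeScanFixture(n = 148, seed = 77,
                        plant = list(m = "cg5", e = "ex5", rho = 0.8))
  res <- scanMethExpr(fx$meth, fx$expr, fx$covar)
  sig <- res$records[res$records$significant, ]
  for (rel in c("cis", "trans")) for (sgn in c("positive", "negative"))
    expect_equal(res$summary[res$summary$relation == rel, sgn],
                 sum(sig$relation == rel & sig$sign == sgn))
})
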