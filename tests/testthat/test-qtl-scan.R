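makeQtlFixture <- function(n = 100, nSnp = 8, seed = 31, effect = 0,
                           maf = 0.3) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  covar <- data.frame(sample_id = samples, age = runif(n, 20, 80),
                      sex = rep(c(0, 1), length.out = n))
  dos <- matrix(rbinom(nSnp * n, 2, maf), nSnp, n,
                dimnames = list(paste0("snp", seq_len(nSnp)), samples))
  geno <- GenotypeSet(dos, rep("chr1", nSnp),
                      as.integer(seq(1e5, by = 2e5, length.out = nSnp)))
  lv <- matrix(rnorm(3 * n), 3, n,
               dimnames = list(paste0("cg", 1:3), samples))
  if (effect != 0)
    lv["cg1", ] <- effect * scale(dos["snp1", ])[, 1] +
      sqrt(1 - effect^2) * rnorm(n)
  ann <- data.frame(probe_id = rownames(lv), chrom = "chr1",
                    pos = c(1e5, 5e5, 9e5), gene_symbol = NA)
  meth <- OmicsSet((lv - min(lv)) / (max(lv) - min(lv)),
                   "methylation_beta", ann, covar)
  list(geno = geno, meth = meth, covar = covar, dosage = dos)
}

test_that("QTL p-values equal linearAssociation applied per SNP", {
  fx <- makeQtlFixture()
  res <- scanQtl(fx$meth, fx$geno, fx$covar)
  covDf <- fx$covar[, c("age", "sex")]
  for (k in seq_len(nrow(res$records))) {
    rec <- res$records[k, ]
    y <- assay(fx$meth)[rec$target_probe, ]
    x <- assay(fx$geno, "dosage")[rec$snp_id, ]
    ref <- linearAssociation(y, x, covDf)
    expect_equal(rec$wald_p, ref$waldP, tolerance = 1e-12)
    expect_equal(rec$coefficient, ref$coefficient, tolerance = 1e-12)
  }
})

test_that("monomorphic SNPs are excluded by the MAF filter", {
  fx <- makeQtlFixture()
  dos <- assay(fx$geno, "dosage")
  dos["snp2", ] <- 0
  rd <- rowData(fx$geno)
  geno <- GenotypeSet(dos, as.character(rd$chrom), rd$pos)
  res <- scanQtl(fx$meth, geno, fx$covar)
  expect_false("snp2" %in% res$records$snp_id)
  expect_equal(res$nSnps, 7)
})

test_that("duplicated dosage vectors yield identical p-values", {
  fx <- makeQtlFixture()
  dos <- assay(fx$geno, "dosage")
  dos["snp3", ] <- dos["snp1", ]
  rd <- rowData(fx$geno)
  geno <- GenotypeSet(dos, as.character(rd$chrom), rd$pos)
  res <- scanQtl(fx$meth, geno, fx$covar)
  r <- res$records
  for (probe in unique(r$target_probe)) {
    p1 <- r$wald_p[r$snp_id == "snp1" & r$target_probe == probe]
    p3 <- r$wald_p[r$snp_id == "snp3" & r$target_probe == probe]
    if (length(p1) && length(p3)) expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("planted cis-mQTL effects are detected at the cis threshold", {
  hits <- vapply(1:20, function(s) {
    fx <- makeQtlFixture(n = 148, seed = 200 + s, effect = 0.5)
    res <- scanQtl(fx$meth, fx$geno, fx$covar)
    r <- res$records
    any(r$snp_id == "snp1" & r$target_probe == "cg1" & r$passes_threshold)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("LD pruning keeps one SNP per correlated block", {
  set.seed(41)
  n <- 120
  base <- rbinom(n, 2, 0.4)
  dup <- rbind(snpA = base, snpB = base)   # r^2 = 1
  colnames(dup) <- paste0("s", 1:n)
  g <- GenotypeSet(dup, c("chr1", "chr1"), c(100L, 200L))
  expect_equal(ldPrune(g), "snpA")   # the later-positioned copy is removed

  # three SNPs pairwise correlated above threshold -> one kept
  noisyCopy <- function(v) ifelse(runif(n) < 0.9, v, rbinom(n, 2, 0.4))
  trio <- rbind(s1 = base, s2 = noisyCopy(base), s3 = noisyCopy(base))
  colnames(trio) <- paste0("s", 1:n)
  cc <- cor(t(trio))^2
  expect_true(all(cc[upper.tri(cc)] > 0.2))   # fixture sanity (fixed seed)
  g3 <- GenotypeSet(trio, rep("chr1", 3), c(100L, 200L, 300L))
  expect_equal(ldPrune(g3), "s1")
})

test_that("independent SNPs survive pruning and the post-condition holds", {
  set.seed(42)
  n <- 200; p <- 30
  dos <- matrix(rbinom(p * n, 2, 0.3), p, n,
                dimnames = list(paste0("snp", 1:p), paste0("s", 1:n)))
  g <- GenotypeSet(dos, rep("chr1", p),
                   as.integer(seq(1000, by = 1000, length.out = p)))
  kept <- ldPrune(g, r2Threshold = 0.2, windowSnps = 10, step = 3)
  # exhaustive post-check within every window of the retained set
  keptIdx <- match(kept, rownames(dos))
  for (start in seq(1, length(keptIdx), by = 3)) {
    win <- keptIdx[start:min(start + 9, length(keptIdx))]
    if (length(win) < 2) next
    r2 <- cor(t(dos[win, , drop = FALSE]))^2
    expect_lte(max(r2[upper.tri(r2)]), 0.2 + 1e-12)
  }
  # mutually independent draws: essentially everything is retained
  expect_gte(length(kept), p - 2)
})

test_that("independent locus counting groups significant SNPs by prune set", {
  qtl <- data.frame(
    snp_id = c("a", "b", "c", "d", "e", "f", "g"),
    target_probe = c(rep("p1", 5), "p2", "p3"),
    passes_threshold = c(rep(TRUE, 5), TRUE, TRUE))
  # five significant SNPs for p1 all in perfect LD: prune keeps only "a"
  res <- independentLoci(qtl, prunedSnps = c("a", "f", "g"))
  expect_equal(res$totalLoci, 3)
  expect_equal(res$probesWithSnp, 3)
  expect_equal(res$perTarget$n_loci[res$perTarget$target_probe == "p1"], 1)

  two <- data.frame(snp_id = c("x", "y"), target_probe = c("p1", "p2"),
                    passes_threshold = TRUE)
  res2 <- independentLoci(two, prunedSnps = c("x", "y"))
  expect_equal(res2$totalLoci, 2)
  expect_equal(res2$probesWithSnp, 2)
})
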