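test_that("TOM matches a brute-force double-loop oracle", {
  set.seed(71)
  dat <- matrix(rnorm(10 * 40), 10, 40,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:40)))
  adj <- networkAdjacency(dat, 6, "unsigned")
  tom <- tomSimilarity(adj)
  expect_equal(tom, oracleTom(adj), tolerance = 1e-12,
               ignore_attr = TRUE)
  # structural properties
  expect_true(isSymmetric(tom))
  expect_true(all(diag(tom) == 1))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("TOM is 1 for duplicated probes and ~0 for independent ones", {
  set.seed(72)
  v <- rnorm(200)
  two <- rbind(a = v, b = v)
  colnames(two) <- paste0("s", 1:200)
  tom2 <- tomSimilarity(networkAdjacency(two, 6, "unsigned"))
  expect_equal(tom2[1, 2], 1, tolerance = 1e-12)

  ind <- matrix(rnorm(5 * 2000), 5, 2000,
                dimnames = list(paste0("p", 1:5), NULL))
  tomI <- tomSimilarity(networkAdjacency(ind, 6, "unsigned"))
  expect_lt(max(abs(tomI[upper.tri(tomI)])), 0.01)

  cst <- rbind(a = rep(1, 10), b = rnorm(10))
  expect_error(networkAdjacency(cst, 6), "a")
})

test_that("signed and unsigned adjacencies follow their formulas", {
  set.seed(73)
  dat <- matrix(rnorm(6 * 30), 6, 30,
                dimnames = list(paste0("p", 1:6), NULL))
  r <- cor(t(dat))
  au <- networkAdjacency(dat, 4, "unsigned")
  as_ <- networkAdjacency(dat, 4, "signed")
  off <- upper.tri(r)
  expect_equal(au[off], (abs(r)^4)[off], tolerance = 1e-12)
  expect_equal(as_[off], (((1 + r) / 2)^4)[off], tolerance = 1e-12)
})

test_that("soft power selection returns a documented fallback on noise", {
  sim <- simulateModules(100, 40, 0.8, 40, seed = 74)
  pick <- suppressWarnings(pickSoftPower(sim$data))
  expect_true(pick$power %in% c(1:10, 12, 14, 16, 18, 20))
  expect_equal(pickSoftPower(sim$data, candidatePowers = 7)$power, 7)
  noise <- matrix(rnorm(30 * 2000), 30, 2000,
                  dimnames = list(paste0("p", 1:30), NULL))
  expect_warning(pickSoftPower(noise, candidatePowers = c(1, 2),
                               targetR2 = 0.999), "target")
})

test_that("module labels are ordered by decreasing size with background 0", {
  sim <- simulateModules(150, c(30, 60), 0.8, 80, seed = 75)
  tom <- tomSimilarity(networkAdjacency(sim$data, 6, "unsigned"))
  lab <- detectModules(tom, minSize = 20)
  expect_error(detectModules(tom, minSize = 1), ">= 2")
  sizes <- table(lab[lab > 0])
  expect_equal(as.integer(names(sizes)), seq_along(sizes))
  expect_true(all(diff(as.integer(sizes)) <= 0))
  # the 60-probe truth block is module 1, the 30-probe block module 2
  expect_gt(sum(lab[sim$labels == 2] == 1), 55)
  expect_gt(sum(lab[sim$labels == 1] == 2), 25)
})

test_that("eigengenes summarize modules and kME covers all probes", {
  set.seed(76)
  v <- rnorm(100)
  data <- rbind(t(sapply(1:10, function(i) v + rnorm(100, 0, 0.05))),
                matrix(rnorm(5 * 100), 5, 100))
  rownames(data) <- paste0("p", 1:15)
  colnames(data) <- paste0("s", 1:100)
  labels <- setNames(c(rep(1L, 10), rep(0L, 5)), rownames(data))
  me <- moduleEigengenes(data, labels)
  expect_gt(me$propVarExplained["ME1"], 0.99)
  expect_true(all(me$kME[1:10, "ME1"] > 0.99))
  expect_equal(dim(me$kME), c(15L, 1L))
  expect_equal(sum(me$eigengenes["ME1", ]^2), 1, tolerance = 1e-10)

  # sign orientation survives wholesale negation of the member profiles
  neg <- data; neg[1:10, ] <- -neg[1:10, ]
  meNeg <- moduleEigengenes(neg, labels)
  expect_true(all(meNeg$kME[1:10, "ME1"] > 0.99))
})

test_that("variance explained matches an independent eigendecomposition", {
  sim <- simulateModules(80, 25, 0.7, 0, seed = 77)
  labels <- setNames(rep(1L, 25), rownames(sim$data))
  me <- moduleEigengenes(sim$data, labels)
  Z <- t(scale(t(sim$data)))
  ev <- eigen(tcrossprod(Z), only.values = TRUE)$values
  expect_equal(unname(me$propVarExplained["ME1"]), ev[1] / sum(ev),
               tolerance = 1e-10)
  # the eigengene beats random unit projections
  best <- me$propVarExplained["ME1"]
  set.seed(78)
  for (k in 1:100) {
    u <- rnorm(ncol(sim$data)); u <- u / sqrt(sum(u^2))
    proj <- as.numeric(Z %*% u)
    expect_lte(sum(proj^2) / sum(Z^2), best + 1e-10)
  }
})

test_that("label matching maps overlapping modules and invents fresh labels", {
  probes <- paste0("g", 1:300)
  ref <- setNames(c(rep(1L, 60), rep(2L, 50), rep(0L, 190)), probes)
  test <- ref   # identical labeling
  m <- matchModuleLabels(ref, test)
  expect_equal(m$mapping$new_label, c(1L, 2L))
  diag_p <- m$overlap$fisher_p[m$overlap$test_module ==
                                 m$overlap$ref_module]
  expect_true(all(diag_p < 1e-10))

  # a test module split across two ref modules goes to the larger overlap
  test2 <- setNames(rep(0L, 300), probes)
  test2[1:40] <- 1L; test2[61:75] <- 1L    # 40 genes in ref1, 15 in ref2
  m2 <- matchModuleLabels(ref, test2)
  expect_equal(m2$mapping$new_label[m2$mapping$test_module == 1], 1L)

  # disjoint labelings get fresh labels beyond the reference range
  test3 <- setNames(rep(0L, 300), probes)
  test3[151:200] <- 1L
  m3 <- matchModuleLabels(ref, test3)
  expect_gt(m3$mapping$new_label[1], 2L)
})

test_that("biweight midcorrelation resists an outlier that drags Pearson", {
  set.seed(79)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.01)
  expect_equal(bicor(x, y), 1, tolerance = 1e-3)
  yOut <- y; yOut[1] <- 100
  expect_gt(bicor(x, yOut), cor(x, yOut))
  expect_warning(b <- bicor(c(rep(0, 49), 1), x), "MAD")

  A <- rbind(e1 = x)
  B <- rbind(m1 = y, m2 = rnorm(50))
  rc <- robustEigengeneCor(A, B)
  expect_lt(rc$p["e1", "m1"], 1e-20)
  expect_gt(rc$p["e1", "m2"], 0.001)
})

test_that("preservation statistics are reproducible and permutation-invariant", {
  sim <- simulateModules(60, c(30), 0.7, 50, seed = 80)
  labels <- sim$labels
  test <- sim$data + matrix(rnorm(length(sim$data), 0, 0.3),
                            nrow(sim$data))
  p1 <- modulePreservation(sim$data, test, labels, nPerm = 50, seed = 5)
  p2 <- modulePreservation(sim$data, test, labels, nPerm = 50, seed = 5)
  expect_identical(p1, p2)

  # joint sample permutation of both datasets leaves the statistics alone
  perm <- sample(ncol(sim$data))
  p3 <- modulePreservation(sim$data[, perm], test[, perm], labels,
                           nPerm = 50, seed = 5)
  expect_equal(p1$Zsummary, p3$Zsummary, tolerance = 1e-10)
  expect_error(modulePreservation(sim$data, test, labels, nPerm = 10),
               ">= 50")
})
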