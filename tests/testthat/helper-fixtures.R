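# Shared fixtures and independent oracles used across the suite.

# random symmetric positive-definite 3x3 covariance
randPD3 <- function() {
  A <- matrix(rnorm(9), 3)
  crossprod(A) + diag(3) * 0.5
}

# Closed-form likelihood-ratio chi-square for each causal model's single
# df=1 constraint, computed from correlations only (independent of the
# package's numerical ML fit):
#   M1: partial cor(S, E | M) = 0;  M2: partial cor(S, M | E) = 0
#   M3: partial cor(M, E | S) = 0;  M4: cor(S, M) = 0;  M5: cor(S, E) = 0
semOracleChisq <- function(modelId, S, n) {
  R <- cov2cor(S)
  pc <- function(i, j, k)
    (R[i, j] - R[i, k] * R[j, k]) / sqrt((1 - R[i, k]^2) * (1 - R[j, k]^2))
  r <- switch(modelId,
    M1 = pc(1, 3, 2), M2 = pc(1, 2, 3), M3 = pc(2, 3, 1),
    M4 = R[1, 2], M5 = R[1, 3])
  -(n - 1) * log(1 - r^2)
}

# model-implied covariance built directly from the path equations (written
# independently of the package internals), unit exogenous variances
oracleImpliedCov <- function(modelId, a, b) {
  switch(modelId,
    M1 = { # S -> M -> E
      sm <- a; mm <- a^2 + 1; se <- a * b; me <- b * mm; ee <- b^2 * mm + 1
      matrix(c(1, sm, se, sm, mm, me, se, me, ee), 3)
    },
    M2 = {
      se <- a; ee <- a^2 + 1; sm <- a * b; me <- b * ee; mm <- b^2 * ee + 1
      matrix(c(1, sm, se, sm, mm, me, se, me, ee), 3)
    },
    M3 = {
      sm <- a; se <- b; mm <- a^2 + 1; ee <- b^2 + 1; me <- a * b
      matrix(c(1, sm, se, sm, mm, me, se, me, ee), 3)
    },
    M4 = {
      sm <- 0; se <- a; me <- b; mm <- 1; ee <- a^2 + b^2 + 1
      matrix(c(1, sm, se, sm, mm, me, se, me, ee), 3)
    },
    M5 = {
      se <- 0; sm <- a; me <- b; ee <- 1; mm <- a^2 + b^2 + 1
      matrix(c(1, sm, se, sm, mm, me, se, me, ee), 3)
    })
}

# brute-force double-loop topological overlap
oracleTom <- function(adj) {
  A <- as.matrix(adj)
  diag(A) <- 0
  p <- nrow(A)
  k <- rowSums(A)
  tom <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(p)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# brute-force inter-array connectivity Z.k
oracleZk <- function(m) {
  n <- ncol(m)
  k <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + cor(m[, i], m[, j])
    k[i] <- s
  }
  (k - mean(k)) / sd(k)
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (probability-mass rule, with the conventional relative tolerance)
oracleFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force Benjamini-Hochberg step-up: returns adjusted values
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# tiny cohort settings used by the pipeline tests
tinyCohortConfig <- function(...) {
  base <- list(nSamples = 60, nMale = 30, nSnps = 60,
               nMethProbes = 300, nExprProbes = 300,
               nCisPairs = 10, nTransPairs = 3,
               triplesPerModel = c(M1 = 2, M2 = 2, M3 = 0, M4 = 0, M5 = 0),
               nMqtlOnly = 5, moduleSizes = c(40), nSharedFactors = 1,
               sharedModuleSize = 30)
  do.call(cohortConfig, utils::modifyList(base, list(...)))
}

writeTempTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
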