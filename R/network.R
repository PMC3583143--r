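# Weighted correlation network analysis: soft-thresholded adjacency,
# topological overlap, tree-cut module detection, eigengenes/kME, label
# matching across datasets, robust eigengene correlation, and permutation
# module preservation.

#' Soft-thresholded network adjacency
#'
#' Unsigned: a_ij = |cor(x_i, x_j)|^beta; signed:
#' a_ij = ((1 + cor) / 2)^beta.  Correlations are across samples between
#' probe profiles.  Diagonal set to 1.
#'
#' @param data probes x samples matrix.
#' @param power soft threshold beta (integer >= 1).
#' @param mode "unsigned" or "signed".
#' @return probes x probes adjacency matrix in \[0, 1\].
#' @export
networkAdjacency <- function(data, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  sds <- apply(data, 1, sd)
  if (any(sds == 0))
    stop("constant probe (undefined correlation): ",
         rownames(data)[which(sds == 0)[1]])
  r <- cor(t(data))
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' sums and connectivities k excluding self terms; TOM_ii = 1.  Combines
#' the direct adjacency of two probes with the adjacency they share with
#' common neighbours.
#'
#' @param adj adjacency matrix from \code{\link{networkAdjacency}}.
#' @return symmetric TOM similarity matrix with unit diagonal.
#' @export
tomSimilarity <- function(adj) {
  A <- as.matrix(adj)
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned
#' (equal-width bins on k), and log10 frequency is regressed on log10 mean
#' connectivity per bin; the scale-free fit index is the R-squared of that
#' regression.  The smallest candidate reaching \code{targetR2} is chosen;
#' if none reaches it, the candidate with maximal R-squared is returned
#' with a warning.
#'
#' @param data probes x samples matrix (>= 20 probes).
#' @param candidatePowers integer vector of candidate betas.
#' @param targetR2 scale-free fit target (default 0.8).
#' @param mode adjacency sign mode.
#' @param nBins connectivity histogram bins.
#' @return list with \code{power}, \code{fitIndices} (power, r2, meanK).
#' @export
pickSoftPower <- function(data, candidatePowers = c(1:10, 12, 14, 16, 18, 20),
                          targetR2 = 0.8, mode = "unsigned", nBins = 10) {
  data <- as.matrix(data)
  if (nrow(data) < 20) stop("need >= 20 probes")
  if (length(candidatePowers) == 1)
    return(list(power = candidatePowers,
                fitIndices = data.frame(power = candidatePowers, r2 = NA,
                                        meanK = NA)))
  r <- cor(t(data))
  fit <- lapply(candidatePowers, function(b) {
    a <- if (mode == "unsigned") abs(r)^b else ((1 + r) / 2)^b
    diag(a) <- 0
    k <- rowSums(a)
    if (max(k) - min(k) < 1e-12) stop("degenerate connectivity (all equal)")
    brk <- seq(min(k), max(k), length.out = nBins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & mk > 0
    x <- log10(mk[ok]); y <- log10(freq[ok] / length(k))
    r2 <- if (length(x) < 3) 0 else suppressWarnings(cor(x, y))^2
    c(r2 = unname(r2), meanK = mean(k))
  })
  fi <- data.frame(power = candidatePowers,
                   r2 = vapply(fit, `[[`, numeric(1), "r2"),
                   meanK = vapply(fit, `[[`, numeric(1), "meanK"))
  hit <- which(fi$r2 >= targetR2)
  if (length(hit)) {
    power <- fi$power[hit[1]]
  } else {
    warning("no candidate power reaches the scale-free fit target; ",
            "using the best-fitting power")
    power <- fi$power[which.max(fi$r2)]
  }
  list(power = power, fitIndices = fi)
}

#' Detect modules as branches of a hierarchical cluster tree
#'
#' Average-linkage clustering on 1 - TOM, with a static cut at the given
#' quantile of merge heights.  Clusters smaller than \code{minSize} are
#' assigned to the unassigned background (label 0).  Module labels are
#' ordered by decreasing size: module 1 is the largest.
#'
#' @param tom TOM similarity matrix.
#' @param minSize minimum module size (default 30).
#' @param heightQuantile quantile of merge heights for the static cut
#'   (default 0.8).
#' @return integer vector of labels, named by probe.
#' @export
detectModules <- function(tom, minSize = 30, heightQuantile = 0.8) {
  if (minSize < 2) stop("minSize must be >= 2")
  d <- as.dist(1 - tom)
  h <- hclust(d, method = "average")
  cutH <- quantile(h$height, heightQuantile)
  raw <- cutree(h, h = cutH)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  labels <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)])]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  names(labels) <- rownames(as.matrix(tom))
  labels
}

#' Module eigengenes, variance explained, and module membership (kME)
#'
#' The eigengene of a module is the first right-singular vector of its
#' probes-standardized matrix (the first principal component across
#' samples), sign-oriented so that the mean correlation of member probes
#' with their eigengene is positive, and scaled to unit norm.  kME is the
#' correlation of every probe (members and non-members alike) with every
#' module eigengene.
#'
#' @param data probes x samples matrix.
#' @param labels integer module labels named by probe (0 = background).
#' @return list with \code{eigengenes} (modules x samples, rownames
#'   "ME<label>"), \code{propVarExplained} (named numeric), \code{kME}
#'   (probes x modules).
#' @export
moduleEigengenes <- function(data, labels) {
  data <- as.matrix(data)
  labels <- labels[rownames(data)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules (all labels 0)")
  nS <- ncol(data)
  eig <- matrix(NA_real_, length(mods), nS,
                dimnames = list(paste0("ME", mods), colnames(data)))
  pve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    members <- which(labels == mods[i])
    if (length(members) < 2) stop("module of size < 2: ", mods[i])
    X <- data[members, , drop = FALSE]
    sds <- apply(X, 1, sd)
    if (any(sds == 0)) stop("zero-variance probe in module ", mods[i])
    Z <- (X - rowMeans(X)) / sds
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(cor(t(X), e)) < 0) e <- -e
    eig[i, ] <- e
    pve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  kME <- cor(t(data), t(eig))
  rownames(kME) <- rownames(data)
  list(eigengenes = eig, propVarExplained = pve, kME = kME)
}

#' Match test module labels to reference labels by overlap significance
#'
#' Cross-tabulates the two labelings on the shared probe universe and
#' computes a Fisher exact p for every (test module, reference module)
#' overlap.  Test modules are greedily assigned the reference label of
#' their most significant overlap (p < 0.05), each reference label used at
#' most once; unmatched test modules keep fresh labels above the largest
#' reference label.  Label 0 (background) is never reassigned.
#'
#' @param refLabels,testLabels integer label vectors named by probe.
#' @return list with \code{labels} (relabeled test vector), \code{overlap}
#'   (data.frame test_module, ref_module, n_overlap, fisher_p),
#'   \code{mapping} (data.frame test_module, new_label).
#' @export
matchModuleLabels <- function(refLabels, testLabels) {
  shared <- intersect(names(refLabels), names(testLabels))
  rl <- refLabels[shared]; tl <- testLabels[shared]
  testMods <- sort(unique(tl[tl > 0]))
  refMods <- sort(unique(rl[rl > 0]))
  rows <- list()
  for (tm in testMods) for (rm in refMods) {
    a <- sum(tl == tm & rl == rm)
    b <- sum(tl == tm & rl != rm)
    cc <- sum(tl != tm & rl == rm)
    dd <- sum(tl != tm & rl != rm)
    p <- fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    rows[[length(rows) + 1L]] <- data.frame(test_module = tm,
                                            ref_module = rm, n_overlap = a,
                                            fisher_p = p)
  }
  overlap <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test_module = integer(), ref_module = integer(),
               n_overlap = integer(), fisher_p = numeric())
  mapping <- data.frame(test_module = testMods,
                        new_label = rep(NA_integer_, length(testMods)))
  usedRef <- integer(0)
  ord <- order(overlap$fisher_p)
  for (k in ord) {
    tm <- overlap$test_module[k]; rm <- overlap$ref_module[k]
    if (overlap$fisher_p[k] >= 0.05) break
    if (rm %in% usedRef) next
    if (!is.na(mapping$new_label[mapping$test_module == tm])) next
    mapping$new_label[mapping$test_module == tm] <- rm
    usedRef <- c(usedRef, rm)
  }
  fresh <- max(c(refMods, 0L)) + 1L
  for (i in seq_len(nrow(mapping))) {
    if (is.na(mapping$new_label[i])) {
      while (fresh %in% c(usedRef, mapping$new_label)) fresh <- fresh + 1L
      mapping$new_label[i] <- fresh
      fresh <- fresh + 1L
    }
  }
  newLabels <- testLabels
  for (i in seq_len(nrow(mapping)))
    newLabels[testLabels == mapping$test_module[i]] <- mapping$new_label[i]
  list(labels = newLabels, overlap = overlap, mapping = mapping)
}

#' Biweight midcorrelation
#'
#' Robust correlation with tuning constant 9 (weights vanish beyond 9 MADs
#' from the median).  Falls back to Pearson with a warning when either
#' vector has zero median absolute deviation.
#'
#' @param x,y numeric vectors of equal length.
#' @return numeric correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  w <- function(v) {
    med <- median(v); s <- mad(v, constant = 1)
    if (s == 0) return(NULL)
    u <- (v - med) / (9 * s)
    wt <- (1 - u^2)^2
    wt[abs(u) >= 1] <- 0
    wt * (v - med)
  }
  wx <- w(x); wy <- w(y)
  if (is.null(wx) || is.null(wy)) {
    warning("zero MAD; falling back to Pearson correlation")
    return(cor(x, y))
  }
  sum(wx * wy) / sqrt(sum(wx^2) * sum(wy^2))
}

#' Robust correlation matrix between two eigengene sets
#'
#' Biweight midcorrelation between every pair of rows, with p-values from
#' the Student-t approximation on n - 2 degrees of freedom.
#'
#' @param eigengenesA,eigengenesB modules x samples matrices over the same
#'   samples.
#' @return list with \code{cor} and \code{p} matrices (rows = A modules,
#'   columns = B modules).
#' @export
robustEigengeneCor <- function(eigengenesA, eigengenesB) {
  A <- as.matrix(eigengenesA); B <- as.matrix(eigengenesB)
  if (ncol(A) != ncol(B)) stop("eigengene sets must share samples")
  n <- ncol(A)
  cc <- matrix(NA_real_, nrow(A), nrow(B),
               dimnames = list(rownames(A), rownames(B)))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    cc[i, j] <- bicor(A[i, ], B[j, ])
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  tt <- cc * sqrt((n - 2) / pmax(1 - cc^2, 1e-300))
  p <- 2 * pt(-abs(tt), n - 2)
  list(cor = cc, p = p)
}

# cross-data statistics of one probe set: 2 density + 3 connectivity
preservationStats <- function(refData, testData, probes, power, mode) {
  Xr <- refData[probes, , drop = FALSE]
  Xt <- testData[probes, , drop = FALSE]
  Ar <- networkAdjacency(Xr, power, mode)
  At <- networkAdjacency(Xt, power, mode)
  off <- upper.tri(At)
  meanAdj <- mean(At[off])
  # variance explained by the test eigengene of the (ref-defined) probe set
  sds <- apply(Xt, 1, sd)
  Z <- (Xt - rowMeans(Xt)) / sds
  sv <- svd(Z, nu = 0, nv = 1)
  pve <- sv$d[1]^2 / sum(sv$d^2)
  e <- sv$v[, 1]
  kMEt <- as.numeric(cor(t(Xt), e))
  svr <- svd((Xr - rowMeans(Xr)) / apply(Xr, 1, sd), nu = 0, nv = 1)
  kMEr <- as.numeric(cor(t(Xr), svr$v[, 1]))
  kIMr <- rowSums(Ar) - 1
  kIMt <- rowSums(At) - 1
  Cr <- cor(t(Xr)); Ct <- cor(t(Xt))
  c(meanAdj = meanAdj, propVarExplained = pve,
    corKIM = cor(kIMr, kIMt),
    corKME = abs(cor(kMEr, kMEt)),
    corCor = cor(Cr[off], Ct[off]))
}

#' Permutation module preservation (Zsummary, medianRank)
#'
#' Asks whether the density and connectivity patterns of modules defined in
#' a reference dataset persist in a test dataset, without re-detecting
#' modules there.  For each reference module the observed statistics are two
#' density measures (mean test adjacency within the module; variance
#' explained by the module's test eigengene) and three connectivity measures
#' (correlation between reference and test intramodular connectivity, kME
#' vectors, and vectorized within-module correlations).  The null is built
#' by recomputing the same statistics on \code{nPerm} random probe sets of
#' equal size drawn from the shared probe universe; each statistic is
#' standardized to a Z score, Zdensity and Zconnectivity are the medians
#' within class, and Zsummary their mean.  Interpretation follows the usual
#' bands: Zsummary < 2 no evidence of preservation, 2-10 weak to moderate,
#' > 10 strong.  medianRank is the median across statistics of the module's
#' rank among all modules (low rank = well preserved) and is insensitive to
#' module size.
#'
#' @param refData,testData probes x samples matrices sharing a probe
#'   universe (intersection used).
#' @param refLabels integer module labels named by probe (0 = background).
#' @param nPerm number of permutations (>= 50; default 200).
#' @param seed RNG seed; output is reproducible for a fixed seed.
#' @param power,mode adjacency parameters used for the preservation
#'   statistics.
#' @return data.frame with one row per module: size, the five observed
#'   statistics, Zdensity, Zconnectivity, Zsummary, medianRank.
#' @export
modulePreservation <- function(refData, testData, refLabels, nPerm = 200,
                               seed = 1, power = 6, mode = "unsigned") {
  if (nPerm < 50) stop("nPerm must be >= 50")
  refData <- as.matrix(refData); testData <- as.matrix(testData)
  shared <- intersect(rownames(refData), rownames(testData))
  if (length(shared) < 10) stop("too few shared probes")
  refData <- refData[shared, , drop = FALSE]
  testData <- testData[shared, , drop = FALSE]
  labels <- refLabels[shared]
  mods <- sort(unique(labels[!is.na(labels) & labels > 0]))
  dropped <- setdiff(sort(unique(refLabels[refLabels > 0])), mods)
  if (length(dropped))
    warning("modules absent from the shared universe skipped: ",
            paste(dropped, collapse = ", "))
  if (!length(mods)) stop("no modules present in the shared universe")
  statNames <- c("meanAdj", "propVarExplained", "corKIM", "corKME", "corCor")
  obs <- t(vapply(mods, function(m)
    preservationStats(refData, testData, names(labels)[labels == m],
                      power, mode), setNames(numeric(5), statNames)))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))

  set.seed(seed)
  permZ <- matrix(NA_real_, length(mods), 5,
                  dimnames = list(NULL, statNames))
  for (i in seq_along(mods)) {
    permStats <- matrix(NA_real_, nPerm, 5)
    for (b in seq_len(nPerm)) {
      probes <- sample(shared, sizes[i])
      permStats[b, ] <- preservationStats(refData, testData, probes,
                                          power, mode)
    }
    mu <- colMeans(permStats); sdv <- apply(permStats, 2, sd)
    z <- (obs[i, ] - mu) / sdv
    # degenerate statistic: the permutation null carries no variance (e.g.
    # ref = test makes every connectivity correlation exactly 1); such
    # components are uninformative and drop out of the class median
    z[sdv < 1e-12] <- NA_real_
    permZ[i, ] <- z
  }
  Zdensity <- apply(permZ[, 1:2, drop = FALSE], 1, median, na.rm = TRUE)
  Zconnectivity <- apply(permZ[, 3:5, drop = FALSE], 1, median, na.rm = TRUE)
  Zsummary <- ifelse(is.na(Zconnectivity), Zdensity,
                     ifelse(is.na(Zdensity), Zconnectivity,
                            (Zdensity + Zconnectivity) / 2))
  # rank modules per observed statistic (1 = highest), median across stats
  rks <- apply(obs, 2, function(v) rank(-v, ties.method = "average"))
  if (is.null(dim(rks))) rks <- matrix(rks, nrow = 1)
  medianRank <- apply(rks, 1, median)
  data.frame(module = mods, size = sizes, obs,
             Zdensity = Zdensity, Zconnectivity = Zconnectivity,
             Zsummary = Zsummary, medianRank = medianRank,
             row.names = NULL)
}
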