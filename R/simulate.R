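# Synthetic multi-omic cohort generation.
#
# The generator emulates the statistical structure the downstream stages
# assume: a cohort of ~148 adults (72 male / 76 female, age uniform on
# 19-88), SNPs in Hardy-Weinberg proportions with MAF >= 5%, methylation
# produced on a latent Gaussian scale and mapped through the logistic
# function to legal beta values, expression on a log2-like Gaussian scale,
# planted cis/trans methylation-expression pairs, planted causal triples
# under each of the five path models, block-correlated module structure in
# both layers (optionally sharing latent factors across layers over
# disjoint probe sets), and CpG island/shore/outside probe classes on a toy
# two-chromosome genome.

#' Simulate one causal triple (SNP, methylation, expression)
#'
#' Draws the SNP as Binomial(2, maf) under Hardy-Weinberg equilibrium and
#' builds the two downstream variables from the standardized dosage
#' according to the requested path model, with residual variances chosen so
#' every downstream variable has unit variance:
#' \itemize{
#'   \item M1 (S->M->E): M = a S' + e, E = b M + e'
#'   \item M2 (S->E->M): E = a S' + e, M = b E + e'
#'   \item M3 (M<-S->E): M = a S' + e, E = b S' + e'
#'   \item M4 (S->E<-M): M ~ N(0,1), E = a S' + b M + e
#'   \item M5 (S->M<-E): E ~ N(0,1), M = a S' + b E + e
#' }
#' where S' = (S - 2 maf) / sqrt(2 maf (1 - maf)).  Chain models require
#' |a| < 1 and |b| < 1; collider models require a^2 + b^2 < 1.
#'
#' @param modelId "M1".."M5".
#' @param n sample size (>= 10).
#' @param maf minor allele frequency in (0, 0.5\].
#' @param a,b path coefficients.
#' @param seed RNG seed (NULL = use the current RNG state).
#' @return list with numeric vectors \code{s} (dosage), \code{m}, \code{e}.
#' @export
simulateCausalTriple <- function(modelId, n, maf, a, b, seed = NULL) {
  modelId <- match.arg(modelId, semModelIds)
  if (n < 10) stop("n must be >= 10")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (!is.finite(a) || !is.finite(b)) stop("a and b must be finite")
  if (modelId %in% c("M1", "M2", "M3")) {
    if (abs(a) >= 1 || abs(b) >= 1)
      stop("|a| and |b| must be < 1 under unit-variance normalization")
  } else if (a^2 + b^2 >= 1) {
    stop("a^2 + b^2 must be < 1 under unit-variance normalization")
  }
  if (!is.null(seed)) set.seed(seed)
  s <- rbinom(n, 2, maf)
  sStd <- (s - 2 * maf) / sqrt(2 * maf * (1 - maf))
  switch(modelId,
    M1 = {
      m <- a * sStd + sqrt(1 - a^2) * rnorm(n)
      e <- b * m + sqrt(1 - b^2) * rnorm(n)
    },
    M2 = {
      e <- a * sStd + sqrt(1 - a^2) * rnorm(n)
      m <- b * e + sqrt(1 - b^2) * rnorm(n)
    },
    M3 = {
      m <- a * sStd + sqrt(1 - a^2) * rnorm(n)
      e <- b * sStd + sqrt(1 - b^2) * rnorm(n)
    },
    M4 = {
      m <- rnorm(n)
      e <- a * sStd + b * m + sqrt(1 - a^2 - b^2) * rnorm(n)
    },
    M5 = {
      e <- rnorm(n)
      m <- a * sStd + b * e + sqrt(1 - a^2 - b^2) * rnorm(n)
    })
  list(s = s, m = m, e = e)
}

#' Simulate block-correlated module structure
#'
#' Each module is driven by one latent factor per sample:
#' x = sqrt(withinCor) factor + sqrt(1 - withinCor) noise, so the expected
#' pairwise correlation of two probes of the same module is
#' \code{withinCor}.  Background probes are pure noise.  Supplying
#' \code{factors} lets two data layers share latent factors over disjoint
#' probe sets.
#'
#' @param nSamples samples (columns).
#' @param moduleSizes integer vector of module sizes (each >= 2).
#' @param withinCor expected within-module correlation in \[0, 1).
#' @param nBackground number of pure-noise probes.
#' @param seed RNG seed (NULL = current state).
#' @param factors optional modules x samples matrix of latent factors to
#'   reuse; default draws fresh standard normals.
#' @param prefix probe id prefix.
#' @return list with \code{data} (probes x samples), \code{labels} (truth),
#'   \code{factors}.
#' @export
simulateModules <- function(nSamples, moduleSizes, withinCor, nBackground,
                            seed = NULL, factors = NULL, prefix = "p") {
  if (any(moduleSizes < 2)) stop("module sizes must be >= 2")
  if (withinCor < 0 || withinCor >= 1) stop("withinCor must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  k <- length(moduleSizes)
  if (is.null(factors))
    factors <- matrix(rnorm(k * nSamples), k, nSamples)
  nProbes <- sum(moduleSizes) + nBackground
  data <- matrix(rnorm(nProbes * nSamples), nProbes, nSamples)
  labels <- integer(nProbes)
  at <- 1L
  for (i in seq_len(k)) {
    idx <- at:(at + moduleSizes[i] - 1L)
    data[idx, ] <- sqrt(withinCor) *
      matrix(factors[i, ], length(idx), nSamples, byrow = TRUE) +
      sqrt(1 - withinCor) * data[idx, , drop = FALSE]
    labels[idx] <- i
    at <- at + moduleSizes[i]
  }
  rownames(data) <- paste0(prefix, seq_len(nProbes))
  colnames(data) <- paste0("s", seq_len(nSamples))
  names(labels) <- rownames(data)
  list(data = data, labels = labels, factors = factors)
}

#' Default cohort simulation settings
#'
#' Returns the settings of the emulated study design: 148 samples (72 male,
#' 76 female), age uniform on 19-88, a toy genome of 2 chromosomes of 10 Mb,
#' 500 SNPs with MAF uniform on \[0.05, 0.5\], 2000 methylation and 2000
#' expression probes.  Planted structure: cis pairs with latent explained
#' variance uniform on \[0.05, 0.5\] and 65% negative; trans pairs with
#' latent explained variance uniform on \[0.23, 0.6\] and 68% positive;
#' causal triples per model with a = b = 0.6 at MAF 0.3; two modules per
#' layer (sizes 50 and 40, within-correlation 0.6) plus optional factors
#' shared across layers over disjoint probes; CpG classes drawn with the
#' array-manifest proportions (island 0.42, shore 0.32, outside 0.26), with
#' an optional shore bias for SNP-driven methylation probes.
#'
#' @param ... overrides of the listed fields.
#' @return named list of settings.
#' @export
cohortConfig <- function(...) {
  defaults <- list(
    nSamples = 148, nMale = 72,
    ageRange = c(19, 88),
    chromosomes = c("chr1", "chr2"), chromLengthBp = 1e7,
    nSnps = 500, mafRange = c(0.05, 0.5),
    nMethProbes = 2000, nExprProbes = 2000,
    nCisPairs = 60, cisR2Range = c(0.05, 0.5), cisNegFrac = 0.65,
    nTransPairs = 10, transR2Range = c(0.23, 0.6), transPosFrac = 0.68,
    triplesPerModel = c(M1 = 3, M2 = 3, M3 = 3, M4 = 3, M5 = 3),
    tripleA = 0.6, tripleB = 0.6, tripleMaf = 0.3,
    nMqtlOnly = 30, mqtlEffect = 0.5,
    moduleSizes = c(50, 40), moduleCor = 0.6, nSharedFactors = 0,
    sharedModuleSize = 40,
    cgiClassProbs = c(island = 0.42, shore = 0.32, outside = 0.26),
    snpShoreBias = 1,
    ageEffect = 0, sexEffect = 0,
    exprBaseMean = 8, exprBaseSd = 1, methBaseSd = 1.5
  )
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown cohort fields: ", paste(bad, collapse = ", "))
  modifyList(defaults, args)
}

# place a probe position of a given CGI class on the regular island grid
# (islands of 1 kb every 50 kb, 1-based [g*50000+1, g*50000+1000])
classPosition <- function(class, chromLength) {
  nIsl <- floor(chromLength / 50000) - 1
  g <- sample.int(nIsl, 1)
  base <- g * 50000
  switch(class,
    island = base + sample.int(1000, 1),
    shore = base + 1000 + sample.int(2000, 1),     # right shore, <= 2 kb out
    outside = base + 3000 + sample.int(50000 - 7000, 1))
}

#' Simulate a full multi-omic cohort
#'
#' Generates genotypes, methylation, expression, probe annotation, CpG
#' island intervals, covariates and ground-truth tables in one call;
#' optionally writes everything to \code{outDir} in the package's file
#' formats (TSV matrices, BED islands, TSV truth tables).
#'
#' Methylation is built on a latent Gaussian scale (baseline + planted
#' signal) and mapped through the logistic function to (0, 1); associations
#' are planted on the latent scale.  Planted probe pools (cis pairs,
#' triples, mQTL-only probes, modules) are disjoint.
#'
#' @param config list from \code{\link{cohortConfig}}.
#' @param seed integer seed; the full output is reproducible given the seed.
#' @param outDir optional directory to write the files into.
#' @return list with \code{genotypes} (\linkS4class{GenotypeSet}),
#'   \code{meth}, \code{expr} (\linkS4class{OmicsSet}s), \code{covariates},
#'   \code{annotationMeth}, \code{annotationExpr}, \code{cgi} (GRanges),
#'   \code{truth} (list of data.frames), and \code{files} when written.
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1,
                           outDir = NULL) {
  set.seed(seed)
  cfg <- config
  nS <- cfg$nSamples
  samples <- sprintf("S%03d", seq_len(nS))
  sex <- c(rep(1, cfg$nMale), rep(0, nS - cfg$nMale))
  covariates <- data.frame(
    sample_id = samples,
    age = round(runif(nS, cfg$ageRange[1], cfg$ageRange[2]), 1),
    sex = sex)

  nTriples <- sum(cfg$triplesPerModel)
  needMeth <- cfg$nCisPairs + cfg$nTransPairs + nTriples + cfg$nMqtlOnly +
    sum(cfg$moduleSizes) + cfg$nSharedFactors * cfg$sharedModuleSize
  needExpr <- cfg$nCisPairs + cfg$nTransPairs + nTriples +
    sum(cfg$moduleSizes) + cfg$nSharedFactors * cfg$sharedModuleSize
  if (needMeth > cfg$nMethProbes || needExpr > cfg$nExprProbes)
    stop("infeasible layout: more planted probes than probes")
  nSnpNeeded <- nTriples + cfg$nMqtlOnly
  if (nSnpNeeded > cfg$nSnps)
    stop("infeasible layout: more planted SNPs than SNPs")

  # --- genotypes: HWE binomial dosages on the toy genome -------------------
  snpIds <- sprintf("snp%04d", seq_len(cfg$nSnps))
  snpChrom <- sample(cfg$chromosomes, cfg$nSnps, replace = TRUE)
  snpPos <- sample.int(cfg$chromLengthBp, cfg$nSnps, replace = TRUE)
  snpMaf <- runif(cfg$nSnps, cfg$mafRange[1], cfg$mafRange[2])
  dosage <- matrix(rbinom(cfg$nSnps * nS, 2, rep(snpMaf, each = nS)),
                   nrow = cfg$nSnps, ncol = nS, byrow = TRUE,
                   dimnames = list(snpIds, samples))

  # --- probe bookkeeping ---------------------------------------------------
  methIds <- sprintf("cg%05d", seq_len(cfg$nMethProbes))
  exprIds <- sprintf("ex%05d", seq_len(cfg$nExprProbes))
  latentM <- matrix(rnorm(cfg$nMethProbes * nS), cfg$nMethProbes, nS,
                    dimnames = list(methIds, samples))
  latentE <- matrix(rnorm(cfg$nExprProbes * nS), cfg$nExprProbes, nS,
                    dimnames = list(exprIds, samples))
  methChrom <- character(cfg$nMethProbes); methPos <- integer(cfg$nMethProbes)
  exprChrom <- character(cfg$nExprProbes); exprPos <- integer(cfg$nExprProbes)
  methClass <- character(cfg$nMethProbes)

  ageZ <- as.numeric(scale(covariates$age))
  sexZ <- as.numeric(scale(covariates$sex))

  # class-dependent position sampler; SNP-driven probes can be biased
  # towards shores via snpShoreBias
  drawClass <- function(n, snpDriven = FALSE) {
    pr <- cfg$cgiClassProbs
    if (snpDriven && cfg$snpShoreBias != 1) {
      pr["shore"] <- pr["shore"] * cfg$snpShoreBias
      pr <- pr / sum(pr)
    }
    sample(names(pr), n, replace = TRUE, prob = pr)
  }
  placeProbe <- function(chrom, class)
    classPosition(class, cfg$chromLengthBp)

  nextMeth <- 1L; nextExpr <- 1L; nextSnp <- 1L
  takeMeth <- function(k) { i <- nextMeth:(nextMeth + k - 1L)
    nextMeth <<- nextMeth + k; i }
  takeExpr <- function(k) { i <- nextExpr:(nextExpr + k - 1L)
    nextExpr <<- nextExpr + k; i }
  takeSnp <- function(k) { i <- nextSnp:(nextSnp + k - 1L)
    nextSnp <<- nextSnp + k; i }

  truthCis <- truthTrans <- truthTriples <- truthMqtl <- NULL

  # --- planted cis / trans methylation-expression pairs --------------------
  plantPair <- function(idxM, idxE, r2, negative, cis) {
    rho <- sqrt(r2) * if (negative) -1 else 1
    base <- latentM[idxM, ]
    latentE[idxE, ] <<- rho * base + sqrt(1 - r2) * rnorm(nS)
    if (cfg$ageEffect != 0) {
      latentM[idxM, ] <<- latentM[idxM, ] + cfg$ageEffect * ageZ
      latentE[idxE, ] <<- latentE[idxE, ] + cfg$ageEffect * ageZ
    }
    if (cfg$sexEffect != 0) {
      latentM[idxM, ] <<- latentM[idxM, ] + cfg$sexEffect * sexZ
      latentE[idxE, ] <<- latentE[idxE, ] + cfg$sexEffect * sexZ
    }
    chrom <- sample(cfg$chromosomes, 1)
    cls <- drawClass(1)
    pM <- placeProbe(chrom, cls)
    methChrom[idxM] <<- chrom; methPos[idxM] <<- pM; methClass[idxM] <<- cls
    if (cis) {
      pE <- pM + sample(seq(-250000, 250000), 1)
      pE <- min(max(pE, 1), cfg$chromLengthBp)
      exprChrom[idxE] <<- chrom
    } else {
      pE <- sample.int(cfg$chromLengthBp, 1)
      exprChrom[idxE] <<- setdiff(cfg$chromosomes, chrom)[1]
    }
    exprPos[idxE] <<- pE
    data.frame(meth_probe = methIds[idxM], expr_probe = exprIds[idxE],
               rho = rho, r2 = r2,
               sign = if (rho < 0) "negative" else "positive")
  }
  if (cfg$nCisPairs > 0) {
    iM <- takeMeth(cfg$nCisPairs); iE <- takeExpr(cfg$nCisPairs)
    r2s <- runif(cfg$nCisPairs, cfg$cisR2Range[1], cfg$cisR2Range[2])
    neg <- runif(cfg$nCisPairs) < cfg$cisNegFrac
    truthCis <- do.call(rbind, lapply(seq_len(cfg$nCisPairs), function(k)
      plantPair(iM[k], iE[k], r2s[k], neg[k], cis = TRUE)))
  }
  if (cfg$nTransPairs > 0) {
    iM <- takeMeth(cfg$nTransPairs); iE <- takeExpr(cfg$nTransPairs)
    r2s <- runif(cfg$nTransPairs, cfg$transR2Range[1], cfg$transR2Range[2])
    neg <- runif(cfg$nTransPairs) >= cfg$transPosFrac
    truthTrans <- do.call(rbind, lapply(seq_len(cfg$nTransPairs), function(k)
      plantPair(iM[k], iE[k], r2s[k], neg[k], cis = FALSE)))
  }

  # --- planted causal triples ---------------------------------------------
  if (nTriples > 0) {
    models <- rep(names(cfg$triplesPerModel), cfg$triplesPerModel)
    iM <- takeMeth(nTriples); iE <- takeExpr(nTriples); iS <- takeSnp(nTriples)
    rows <- list()
    for (k in seq_along(models)) {
      tri <- simulateCausalTriple(models[k], nS, cfg$tripleMaf,
                                  cfg$tripleA, cfg$tripleB)
      dosage[iS[k], ] <- tri$s
      snpMaf[iS[k]] <- cfg$tripleMaf
      latentM[iM[k], ] <- tri$m
      latentE[iE[k], ] <- tri$e
      chrom <- sample(cfg$chromosomes, 1)
      cls <- drawClass(1, snpDriven = TRUE)
      pM <- placeProbe(chrom, cls)
      methChrom[iM[k]] <- chrom; methPos[iM[k]] <- pM
      methClass[iM[k]] <- cls
      pE <- min(max(pM + sample(seq(-200000, 200000), 1), 1),
                cfg$chromLengthBp)
      exprChrom[iE[k]] <- chrom; exprPos[iE[k]] <- pE
      snpChrom[iS[k]] <- chrom
      snpPos[iS[k]] <- min(max(pM + sample(seq(-200000, 200000), 1), 1),
                           cfg$chromLengthBp)
      rows[[k]] <- data.frame(snp = snpIds[iS[k]], meth_probe = methIds[iM[k]],
                              expr_probe = exprIds[iE[k]],
                              model = models[k], a = cfg$tripleA,
                              b = cfg$tripleB)
    }
    truthTriples <- do.call(rbind, rows)
  }

  # --- mQTL-only probes (SNP-driven methylation, no expression link) ------
  if (cfg$nMqtlOnly > 0) {
    iM <- takeMeth(cfg$nMqtlOnly); iS <- takeSnp(cfg$nMqtlOnly)
    rows <- list()
    for (k in seq_len(cfg$nMqtlOnly)) {
      maf <- snpMaf[iS[k]]
      sStd <- (dosage[iS[k], ] - 2 * maf) / sqrt(2 * maf * (1 - maf))
      latentM[iM[k], ] <- cfg$mqtlEffect * sStd +
        sqrt(1 - cfg$mqtlEffect^2) * rnorm(nS)
      chrom <- snpChrom[iS[k]]
      cls <- drawClass(1, snpDriven = TRUE)
      pM <- placeProbe(chrom, cls)
      methChrom[iM[k]] <- chrom; methPos[iM[k]] <- pM
      methClass[iM[k]] <- cls
      snpPos[iS[k]] <- min(max(pM + sample(seq(-200000, 200000), 1), 1),
                           cfg$chromLengthBp)
      rows[[k]] <- data.frame(snp = snpIds[iS[k]],
                              meth_probe = methIds[iM[k]],
                              effect = cfg$mqtlEffect)
    }
    truthMqtl <- do.call(rbind, rows)
  }

  # --- module structure ----------------------------------------------------
  truthModM <- truthModE <- NULL
  modLabelsM <- integer(cfg$nMethProbes); modLabelsE <- integer(cfg$nExprProbes)
  if (length(cfg$moduleSizes) || cfg$nSharedFactors > 0) {
    kOwn <- length(cfg$moduleSizes)
    sizesM <- c(cfg$moduleSizes,
                rep(cfg$sharedModuleSize, cfg$nSharedFactors))
    sizesE <- sizesM
    kAll <- length(sizesM)
    factorsM <- matrix(rnorm(kAll * nS), kAll, nS)
    factorsE <- matrix(rnorm(kAll * nS), kAll, nS)
    if (cfg$nSharedFactors > 0) {
      shIdx <- kOwn + seq_len(cfg$nSharedFactors)
      factorsE[shIdx, ] <- factorsM[shIdx, ]   # same factor, disjoint probes
    }
    w <- cfg$moduleCor
    for (i in seq_len(kAll)) {
      idx <- takeMeth(sizesM[i])
      latentM[idx, ] <- sqrt(w) *
        matrix(factorsM[i, ], length(idx), nS, byrow = TRUE) +
        sqrt(1 - w) * latentM[idx, , drop = FALSE]
      modLabelsM[idx] <- i
      idx <- takeExpr(sizesE[i])
      latentE[idx, ] <- sqrt(w) *
        matrix(factorsE[i, ], length(idx), nS, byrow = TRUE) +
        sqrt(1 - w) * latentE[idx, , drop = FALSE]
      modLabelsE[idx] <- i
    }
    truthModM <- data.frame(probe_id = methIds, module = modLabelsM)
    truthModE <- data.frame(probe_id = exprIds, module = modLabelsE)
  }

  # --- remaining probes: background coordinates and classes ----------------
  todoM <- which(methPos == 0L | is.na(methPos))
  for (i in todoM) {
    methChrom[i] <- sample(cfg$chromosomes, 1)
    cls <- drawClass(1)
    methPos[i] <- classPosition(cls, cfg$chromLengthBp)
    methClass[i] <- cls
  }
  todoE <- which(exprPos == 0L | is.na(exprPos))
  for (i in todoE) {
    exprChrom[i] <- sample(cfg$chromosomes, 1)
    exprPos[i] <- sample.int(cfg$chromLengthBp, 1)
  }

  # --- assemble outputs ----------------------------------------------------
  methBeta <- stats::plogis(cfg$methBaseSd *
                              (latentM + rnorm(cfg$nMethProbes, 0, 0.5)))
  exprMat <- cfg$exprBaseMean +
    rnorm(cfg$nExprProbes, 0, cfg$exprBaseSd) + latentE
  # both layers draw gene symbols from one shared pool, paired at random,
  # so cross-layer gene overlap of planted modules is hypergeometric-null
  genePool <- sprintf("GENE%05d", seq_len(max(cfg$nMethProbes,
                                              cfg$nExprProbes)))
  annM <- data.frame(probe_id = methIds, chrom = methChrom, pos = methPos,
                     gene_symbol = sample(genePool, cfg$nMethProbes))
  annE <- data.frame(probe_id = exprIds, chrom = exprChrom, pos = exprPos,
                     gene_symbol = sample(genePool, cfg$nExprProbes))
  cgi <- cgiIslandGrid(cfg$chromosomes, cfg$chromLengthBp)
  genotypes <- GenotypeSet(dosage, snpChrom, snpPos)
  meth <- OmicsSet(methBeta, "methylation_beta", annotation = annM,
                   covariates = covariates)
  expr <- OmicsSet(exprMat, "expression_log2", annotation = annE,
                   covariates = covariates)
  truthShared <- if (cfg$nSharedFactors > 0)
    data.frame(module = length(cfg$moduleSizes) + seq_len(cfg$nSharedFactors))
  else NULL
  truth <- list(cisPairs = truthCis, transPairs = truthTrans,
                triples = truthTriples, mqtl = truthMqtl,
                modulesMeth = truthModM, modulesExpr = truthModE,
                sharedModules = truthShared,
                methClass = data.frame(probe_id = methIds,
                                       region = methClass))
  out <- list(genotypes = genotypes, meth = meth, expr = expr,
              covariates = covariates, annotationMeth = annM,
              annotationExpr = annE, cgi = cgi, truth = truth)
  if (!is.null(outDir)) out$files <- writeCohort(out, outDir)
  out
}

# regular island grid used by the toy genome: 1 kb islands every 50 kb
cgiIslandGrid <- function(chromosomes, chromLength) {
  nIsl <- floor(chromLength / 50000) - 1
  starts <- (seq_len(nIsl)) * 50000 + 1
  gr <- GRanges(rep(chromosomes, each = nIsl),
                IRanges(rep(starts, length(chromosomes)),
                        rep(starts + 999, length(chromosomes))))
  reduce(GenomicRanges::sort(gr))
}

writeCohort <- function(cohort, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(outDir, name)
  # genotype TSV dialect
  G <- assay(cohort$genotypes, "dosage")
  rd <- rowData(cohort$genotypes)
  gdf <- data.frame(snp_id = rownames(G), chrom = rd$chrom, pos = rd$pos,
                    G, check.names = FALSE)
  write.table(gdf, f("genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeOmicsMatrix(cohort$meth, f("methylation.tsv"))
  writeOmicsMatrix(cohort$expr, f("expression.tsv"))
  writeResultTable(cohort$annotationMeth, f("annotation_meth.tsv"))
  writeResultTable(cohort$annotationExpr, f("annotation_expr.tsv"))
  writeResultTable(cohort$covariates, f("covariates.tsv"))
  bed <- data.frame(chrom = as.character(seqnames(cohort$cgi)),
                    start = start(cohort$cgi) - 1L, end = end(cohort$cgi))
  write.table(bed, f("cgi.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  files <- c(genotypes = f("genotypes.tsv"), methylation = f("methylation.tsv"),
             expression = f("expression.tsv"),
             annotation_meth = f("annotation_meth.tsv"),
             annotation_expr = f("annotation_expr.tsv"),
             covariates = f("covariates.tsv"), cgi = f("cgi.bed"))
  for (nm in names(cohort$truth)) {
    tt <- cohort$truth[[nm]]
    if (is.null(tt)) next
    path <- f(paste0("truth_", nm, ".tsv"))
    writeResultTable(tt, path)
    files[paste0("truth_", nm)] <- path
  }
  files
}
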