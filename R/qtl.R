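#' Scan SNP associations with methylation or expression levels
#'
#' Additive-dosage OLS of each probe level (outcome) on each SNP dosage with
#' age and sex as covariates, sharing the algebra of
#' \code{\link{linearAssociation}}.  SNPs are first filtered to
#' \code{maf >= config@mafMin}.  Cis pairs (same chromosome, within the cis
#' window) are significant at \code{p <= alpha / n_probes}; trans pairs at
#' \code{p <= alpha / (n_probes * n_snps)}.  Trans enumeration is off by
#' default (the analysis focuses on local genetic control).
#'
#' @param levels annotated \linkS4class{OmicsSet}; typically the probes
#'   already implicated in significant methylation-expression pairs.
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param covariates data.frame with sample_id, age, sex (or NULL to use the
#'   colData of \code{levels}).
#' @param config an \linkS4class{AnalysisConfig}.
#' @param transScan also enumerate trans pairs (default FALSE).
#' @return list with \code{records} (snp_id, target_probe, target_kind,
#'   relation, coefficient, se, wald_p, passes_threshold) and \code{nSnps},
#'   \code{nProbes} used for the thresholds.
#' @export
scanQtl <- function(levels, genotypes, covariates = NULL,
                    config = analysisConfig(), transScan = FALSE) {
  keep <- rowData(genotypes)$maf >= config@mafMin
  genotypes <- genotypes[keep, ]
  if (nrow(genotypes) == 0) stop("no SNP passes the MAF filter")
  al <- alignGenoLayer(levels, genotypes, covariates)
  Y <- assay(al$levels, "values")
  G <- assay(al$genotypes, "dosage")
  n <- ncol(Y)
  q <- covariateQr(al$covariates, n)
  RY <- residualMatrix(Y, q)
  RG <- residualMatrix(G, q)
  df <- n - (q$rank + 1L)
  yTss <- apply(Y, 1, function(v) sum((v - mean(v))^2))
  ann <- probeAnnotation(al$levels)
  rdG <- rowData(al$genotypes)

  cis <- cisPairsIdx(as.character(rdG$chrom), rdG$pos, ann$chrom, ann$pos,
                     config@cisWindowBp)
  kind <- if (omicsKind(levels) == "methylation_beta") "methylation"
          else "expression"
  cisThr <- config@alpha / nrow(Y)
  transThr <- config@alpha / (as.numeric(nrow(Y)) * nrow(G))

  build <- function(pairsIJ, relation, thr) {
    st <- pairStats(RY, RG, pairsIJ, df, n, yTss)
    data.frame(snp_id = rownames(G)[pairsIJ[, "i"]],
               target_probe = rownames(Y)[pairsIJ[, "j"]],
               target_kind = kind, relation = relation,
               st[, c("coefficient", "se")], wald_p = st$waldP,
               passes_threshold = st$waldP <= thr, stringsAsFactors = FALSE)
  }
  records <- NULL
  if (nrow(cis) > 0) records <- build(cis, "cis", cisThr)
  else warning("no SNP within the cis window of any probe")

  if (transScan) {
    all <- expand.grid(i = seq_len(nrow(G)), j = seq_len(nrow(Y)))
    rel <- classifyCisTrans(as.character(rdG$chrom)[all$i], rdG$pos[all$i],
                            ann$chrom[all$j], ann$pos[all$j],
                            config@cisWindowBp)
    tp <- as.matrix(all[rel == "trans", , drop = FALSE])
    colnames(tp) <- c("i", "j")
    if (nrow(tp) > 0) records <- rbind(records, build(tp, "trans", transThr))
  }
  if (is.null(records))
    records <- data.frame(snp_id = character(), target_probe = character(),
                          target_kind = character(), relation = character(),
                          coefficient = numeric(), se = numeric(),
                          wald_p = numeric(), passes_threshold = logical())
  rownames(records) <- NULL
  list(records = records, nSnps = nrow(G), nProbes = nrow(Y),
       cisThreshold = cisThr, transThreshold = transThr)
}

alignGenoLayer <- function(levels, genotypes, covariates = NULL) {
  if (is.null(covariates)) {
    cd <- colData(levels)
    if (all(c("age", "sex") %in% colnames(cd)))
      covariates <- data.frame(sample_id = rownames(cd), age = cd$age,
                               sex = cd$sex, stringsAsFactors = FALSE)
  } else {
    covariates <- validateCovariates(as.data.frame(covariates))
  }
  shared <- intersect(colnames(levels), colnames(genotypes))
  if (!is.null(covariates)) shared <- intersect(covariates$sample_id, shared)
  if (length(shared) < 4) stop("too few shared samples across layers")
  ord <- if (!is.null(covariates))
    covariates$sample_id[covariates$sample_id %in% shared] else shared
  covOut <- NULL
  if (!is.null(covariates)) {
    idx <- match(ord, covariates$sample_id)
    covOut <- data.frame(age = covariates$age[idx], sex = covariates$sex[idx])
  }
  list(levels = levels[, ord], genotypes = genotypes[, ord],
       covariates = covOut)
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of \code{windowSnps} SNPs (ordered by
#' chromosome and position), pairs with squared Pearson dosage correlation
#' above \code{r2Threshold} are resolved by removing the later-positioned
#' SNP, repeatedly, until no offending pair remains; the window then slides
#' by \code{step} SNPs.  Deterministic for a given input.
#'
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param r2Threshold prune above this r-squared (default 0.2).
#' @param windowSnps,step window size and slide in SNP count.
#' @return character vector of retained SNP ids, in genomic order.
#' @export
ldPrune <- function(genotypes, r2Threshold = 0.2, windowSnps = 50, step = 5) {
  rd <- rowData(genotypes)
  G <- assay(genotypes, "dosage")
  kept <- character(0)
  for (ch in unique(as.character(rd$chrom))) {
    idx <- which(as.character(rd$chrom) == ch)
    idx <- idx[order(rd$pos[idx])]
    alive <- rep(TRUE, length(idx))
    start <- 1L
    repeat {
      win <- which(alive)
      win <- win[win >= start]
      win <- head(win, windowSnps)
      if (length(win) >= 2) {
        sub <- t(G[idx[win], , drop = FALSE])
        repeat {
          r2 <- suppressWarnings(cor(sub))^2
          r2[!is.finite(r2)] <- 0
          r2[upper.tri(r2, diag = TRUE)] <- 0   # keep (j > i) in lower tri
          off <- which(r2 > r2Threshold, arr.ind = TRUE)
          if (nrow(off) == 0) break
          # first offending pair in column-major order; drop the
          # later-positioned member (the larger index)
          drop <- max(off[1, ])
          alive[win[drop]] <- FALSE
          win <- win[-drop]
          sub <- sub[, -drop, drop = FALSE]
          if (length(win) < 2) break
        }
      }
      if (start + windowSnps - 1 >= length(idx)) break
      start <- start + step
    }
    kept <- c(kept, rownames(G)[idx[alive]])
  }
  kept
}

#' Count independent loci among significant QTL records
#'
#' Restricts significant records to SNPs surviving LD pruning, then counts
#' per target probe the surviving SNPs, the probes with at least one
#' significant SNP, and the total independent loci (unique pruned SNPs over
#' all targets).
#'
#' @param qtlRecords records data.frame from \code{\link{scanQtl}}.
#' @param prunedSnps character vector from \code{\link{ldPrune}}.
#' @return list with \code{perTarget} (data.frame target_probe, n_loci),
#'   \code{probesWithSnp}, \code{totalLoci}.
#' @export
independentLoci <- function(qtlRecords, prunedSnps) {
  sig <- qtlRecords[qtlRecords$passes_threshold, , drop = FALSE]
  probesWithSnp <- length(unique(sig$target_probe))
  sig <- sig[sig$snp_id %in% prunedSnps, , drop = FALSE]
  perTarget <- if (nrow(sig) == 0)
    data.frame(target_probe = character(), n_loci = integer())
  else {
    agg <- aggregate(snp_id ~ target_probe, data = sig,
                     FUN = function(v) length(unique(v)))
    data.frame(target_probe = agg$target_probe, n_loci = agg$snp_id)
  }
  list(perTarget = perTarget, probesWithSnp = probesWithSnp,
       totalLoci = length(unique(sig$snp_id)))
}
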