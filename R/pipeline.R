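# End-to-end orchestration: QC -> association scan -> QTL scan -> CGI
# enrichment -> causal LEO -> network modules -> cross-data preservation,
# with TSV/JSON outputs and a run manifest.

# one seed in the config fans out to per-stage child seeds so stages are
# independently reproducible
stageSeed <- function(seed, stageIndex) {
  as.integer((as.numeric(seed) * 7919 + stageIndex * 104729) %% 2147483629)
}

#' Run the full integrative analysis on a cohort directory
#'
#' Expects the file layout written by \code{\link{simulateCohort}}:
#' \code{genotypes.tsv}, \code{methylation.tsv}, \code{expression.tsv},
#' \code{annotation_meth.tsv}, \code{annotation_expr.tsv},
#' \code{covariates.tsv}, \code{cgi.bed}, and optional \code{truth_*.tsv}
#' tables.  Stages: sample QC (inter-array Z.k outlier removal on the
#' methylation layer), methylation-expression association scan, cis QTL
#' scan of the implicated probes, CpG island/shore enrichment of the
#' result sets, causal LEO screening of shared-SNP triples, module
#' detection in both layers with label matching and robust eigengene
#' correlation, and two-way permutation module preservation.  Outputs are
#' written to \code{outDir} as stages complete; a stage failure halts the
#' run with a stage-named error, retaining earlier outputs.
#'
#' @param inputDir directory with the input files.
#' @param outDir output directory (created).
#' @param config an \linkS4class{AnalysisConfig}.
#' @param nPermPreservation override of \code{config@nPerm} for the
#'   preservation stage.
#' @return (invisibly) a results bundle: list with the per-stage tables and
#'   the paths written.
#' @export
runPipeline <- function(inputDir, outDir, config = analysisConfig(),
                        nPermPreservation = config@nPerm) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 2)
    res
  }
  f <- function(name) file.path(inputDir, name)
  o <- function(name) file.path(outDir, name)

  inputs <- stage("read", {
    covariates <- readCovariates(f("covariates.tsv"))
    annM <- readProbeAnnotation(f("annotation_meth.tsv"))
    annE <- readProbeAnnotation(f("annotation_expr.tsv"))
    list(
      covariates = covariates, annM = annM, annE = annE,
      meth = readOmicsMatrix(f("methylation.tsv"), "methylation_beta",
                             annotation = annM, covariates = covariates),
      expr = readOmicsMatrix(f("expression.tsv"), "expression_log2",
                             annotation = annE, covariates = covariates),
      genotypes = readGenotypes(f("genotypes.tsv"), "tsv"),
      cgi = readCgiBed(f("cgi.bed")))
  })

  qc <- stage("qc", {
    zk <- zkOutliers(assay(inputs$meth, "values"), config@zkThreshold)
    keep <- setdiff(colnames(inputs$meth), zk$flagged)
    writeResultTable(data.frame(sample_id = names(zk$zk), zk = zk$zk,
                                flagged = names(zk$zk) %in% zk$flagged),
                     o("qc_zk.tsv"))
    list(zk = zk, keep = keep)
  })
  covar <- inputs$covariates[inputs$covariates$sample_id %in% qc$keep, ]
  meth <- inputs$meth[, qc$keep]
  expr <- inputs$expr[, qc$keep]
  genotypes <- inputs$genotypes[, qc$keep]

  assoc <- stage("assoc", {
    res <- scanMethExpr(meth, expr, covariates = covar, config = config)
    writeResultTable(res$records, o("assoc_records.tsv"))
    writeResultTable(res$summary, o("assoc_summary.tsv"))
    res
  })
  sig <- assoc$records[assoc$records$significant, , drop = FALSE]
  sigCis <- sig[sig$relation == "cis", , drop = FALSE]

  qtl <- stage("qtl", {
    mProbes <- unique(sig$meth_probe)
    eProbes <- unique(sig$expr_probe)
    if (!length(mProbes) || !length(eProbes)) {
      warning("no significant association pairs; QTL scan skipped")
      empty <- list(records = data.frame(), nSnps = 0, nProbes = 0)
      list(meth = empty, expr = empty, pruned = character(0),
           lociMeth = NULL, lociExpr = NULL)
    } else {
      qm <- scanQtl(meth[mProbes, ], genotypes, covariates = covar,
                    config = config)
      qe <- scanQtl(expr[eProbes, ], genotypes, covariates = covar,
                    config = config)
      pruned <- ldPrune(genotypes, r2Threshold = config@ldR2)
      writeResultTable(qm$records, o("qtl_meth.tsv"))
      writeResultTable(qe$records, o("qtl_expr.tsv"))
      list(meth = qm, expr = qe, pruned = pruned,
           lociMeth = independentLoci(qm$records, pruned),
           lociExpr = independentLoci(qe$records, pruned))
    }
  })

  enrich <- stage("enrich", {
    regions <- classifyRegion(inputs$annM, inputs$cgi, config@shoreBp)
    writeResultTable(regions, o("regions_meth.tsv"))
    sets <- list()
    if (nrow(sigCis)) sets$meth_cis <- unique(sigCis$meth_probe)
    sigTrans <- sig[sig$relation == "trans", , drop = FALSE]
    if (nrow(sigTrans)) sets$meth_trans <- unique(sigTrans$meth_probe)
    if (!is.null(qtl$meth$records) && NROW(qtl$meth$records)) {
      qmSig <- qtl$meth$records[qtl$meth$records$passes_threshold, ]
      snpCis <- intersect(unique(qmSig$target_probe),
                          unique(sigCis$meth_probe))
      if (length(snpCis)) sets$meth_cis_snp <- snpCis
    }
    if (!length(sets)) {
      warning("no significant probe sets; enrichment skipped")
      NULL
    } else {
      rep <- enrichmentReport(sets, inputs$annM$probe_id, regions)
      writeResultTable(rep, o("enrichment.tsv"))
      rep
    }
  })

  causal <- stage("causal", {
    if (!NROW(sigCis) || !NROW(qtl$meth$records) ||
        !NROW(qtl$expr$records)) {
      list(triples = data.frame(), summary = data.frame(
        model = c("M1", "M2"), n_pass = c(0L, 0L)))
    } else {
      res <- screenTriples(assoc$records, qtl$meth$records,
                           qtl$expr$records, genotypes, meth, expr,
                           covariates = covar, config = config)
      if (NROW(res$triples)) writeResultTable(res$triples, o("leo.tsv"))
      writeResultTable(res$summary, o("leo_summary.tsv"))
      res
    }
  })

  network <- stage("network", {
    nets <- lapply(list(meth = assay(meth, "values"),
                        expr = assay(expr, "values")), function(dat) {
      beta <- if (is.na(config@softPower))
        pickSoftPower(dat, mode = config@networkSign)$power
        else config@softPower
      adj <- networkAdjacency(dat, beta, config@networkSign)
      tom <- tomSimilarity(adj)
      labels <- detectModules(tom, config@minModuleSize,
                              config@cutHeightQuantile)
      me <- if (any(labels > 0)) moduleEigengenes(dat, labels) else NULL
      list(power = beta, labels = labels, me = me)
    })
    match <- NULL; eigCor <- NULL
    if (!is.null(nets$meth$me) && !is.null(nets$expr$me)) {
      # module matching is at gene level: the two layers measure different
      # probes but share the gene universe
      match <- matchModuleLabels(
        toGeneLabels(nets$expr$labels, inputs$annE),
        toGeneLabels(nets$meth$labels, inputs$annM))
      eigCor <- robustEigengeneCor(nets$expr$me$eigengenes,
                                   nets$meth$me$eigengenes)
      writeResultTable(match$overlap, o("module_overlap.tsv"))
    }
    for (layer in names(nets)) {
      writeResultTable(data.frame(probe_id = names(nets[[layer]]$labels),
                                  module = nets[[layer]]$labels),
                       o(paste0("modules_", layer, ".tsv")))
      if (!is.null(nets[[layer]]$me)) {
        eg <- nets[[layer]]$me$eigengenes
        writeResultTable(data.frame(module = rownames(eg), eg,
                                    check.names = FALSE),
                         o(paste0("eigengenes_", layer, ".tsv")))
        kme <- nets[[layer]]$me$kME
        writeResultTable(data.frame(probe_id = rownames(kme), kme,
                                    check.names = FALSE),
                         o(paste0("kme_", layer, ".tsv")))
      }
    }
    list(nets = nets, match = match, eigCor = eigCor)
  })

  preserve <- stage("preserve", {
    out <- list()
    nets <- network$nets
    # cross-layer preservation runs on gene-level matrices (one probe per
    # gene) so the two layers share a feature universe
    gMeth <- toGeneMatrix(assay(meth, "values"), inputs$annM)
    gExpr <- toGeneMatrix(assay(expr, "values"), inputs$annE)
    if (!is.null(nets$expr$me) && any(nets$expr$labels > 0))
      out$exprInMeth <- modulePreservation(
        gExpr, gMeth, toGeneLabels(nets$expr$labels, inputs$annE),
        nPerm = nPermPreservation, seed = stageSeed(config@seed, 7),
        power = nets$expr$power, mode = config@networkSign)
    if (!is.null(nets$meth$me) && any(nets$meth$labels > 0))
      out$methInExpr <- modulePreservation(
        gMeth, gExpr, toGeneLabels(nets$meth$labels, inputs$annM),
        nPerm = nPermPreservation, seed = stageSeed(config@seed, 8),
        power = nets$meth$power, mode = config@networkSign)
    for (nm in names(out))
      writeResultTable(out[[nm]], o(paste0("preservation_", nm, ".tsv")))
    out
  })

  truth <- readTruthTables(inputDir)
  scorecard <- if (length(truth))
    stage("scorecard", {
      sc <- truthScorecard(truth, assoc, qtl, causal, network)
      writeResultTable(sc, o("scorecard.tsv"))
      sc
    }) else NULL

  bundle <- list(inputs = inputs, qc = qc, assoc = assoc, qtl = qtl,
                 enrich = enrich, causal = causal, network = network,
                 preserve = preserve, scorecard = scorecard,
                 outDir = outDir)
  report <- pipelineReport(bundle)
  writeLines(report, o("report.txt"))
  manifest <- list(
    config = lapply(configAsList(config), function(v)
      if (is.numeric(v) && is.infinite(v)) "Inf" else v),
    seed = config@seed,
    inputs = as.list(tools::md5sum(list.files(inputDir, full.names = TRUE))),
    timings = timings,
    versions = list(R = R.version.string,
                    omicsTrio = as.character(utils::packageVersion("omicsTrio"))),
    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(manifest, o("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  summaryJson <- list(
    n_samples = length(qc$keep),
    assoc = assoc$summary,
    leo = causal$summary,
    qtl = list(meth_loci = qtl$lociMeth$totalLoci,
               expr_loci = qtl$lociExpr$totalLoci))
  jsonlite::write_json(summaryJson, o("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(bundle)
}

# rename probe-level rows to gene symbols, keeping the first probe per gene
toGeneMatrix <- function(m, annotation) {
  idx <- match(rownames(m), annotation$probe_id)
  gene <- annotation$gene_symbol[idx]
  ok <- !is.na(gene) & !duplicated(gene)
  out <- m[ok, , drop = FALSE]
  rownames(out) <- gene[ok]
  out
}

toGeneLabels <- function(labels, annotation) {
  idx <- match(names(labels), annotation$probe_id)
  gene <- annotation$gene_symbol[idx]
  ok <- !is.na(gene) & !duplicated(gene)
  out <- labels[ok]
  names(out) <- gene[ok]
  out
}

readTruthTables <- function(inputDir) {
  files <- list.files(inputDir, pattern = "^truth_.*\\.tsv$",
                      full.names = TRUE)
  out <- lapply(files, read.table, sep = "\t", header = TRUE,
                stringsAsFactors = FALSE)
  names(out) <- sub("^truth_(.*)\\.tsv$", "\\1",  basename(files))
  out
}

# sensitivity/precision of the run against the planted truth
truthScorecard <- function(truth, assoc, qtl, causal, network) {
  rows <- list()
  sig <- assoc$records[assoc$records$significant, , drop = FALSE]
  addRow <- function(class, tp, nTruth, nCalled)
    rows[[length(rows) + 1L]] <<- data.frame(
      effect_class = class, n_truth = nTruth, n_called = nCalled,
      true_positive = tp,
      sensitivity = if (!is.na(nTruth) && nTruth > 0) tp / nTruth
                    else NA_real_,
      precision = if (!is.na(nCalled) && nCalled > 0) tp / nCalled
                  else NA_real_)
  # pairs induced by latent factors shared across the two layers are real
  # planted correlations, not false positives; exclude them from precision
  inducedKey <- character(0)
  if (!is.null(truth$sharedModules) && !is.null(truth$modulesMeth)) {
    sh <- truth$sharedModules$module
    mP <- truth$modulesMeth$probe_id[truth$modulesMeth$module %in% sh]
    eP <- truth$modulesExpr$probe_id[truth$modulesExpr$module %in% sh]
    inducedKey <- as.vector(outer(mP, eP, paste))
  }
  for (rel in c("cis", "trans")) {
    tt <- truth[[paste0(rel, "Pairs")]]
    if (is.null(tt)) next
    called <- sig[sig$relation == rel, , drop = FALSE]
    key <- paste(called$meth_probe, called$expr_probe)
    induced <- sum(key %in% inducedKey)
    tp <- sum(paste(tt$meth_probe, tt$expr_probe) %in% key)
    addRow(paste0(rel, "_pairs"), tp, nrow(tt), nrow(called) - induced)
    if (induced > 0)
      addRow(paste0(rel, "_module_induced"), induced, NA_integer_, induced)
  }
  if (!is.null(truth$triples) && NROW(causal$triples)) {
    tt <- truth$triples
    focal <- tt[tt$model %in% c("M1", "M2"), , drop = FALSE]
    tr <- causal$triples
    key <- paste(tr$snp_id, tr$meth_probe, tr$expr_probe)
    idx <- match(paste(focal$snp, focal$meth_probe, focal$expr_probe), key)
    found <- !is.na(idx)
    correct <- sum(found &
      ((focal$model == "M1" & tr$pass_m1[idx] %in% TRUE) |
       (focal$model == "M2" & tr$pass_m2[idx] %in% TRUE)))
    addRow("causal_direction", correct, nrow(focal), sum(found))
  }
  if (!is.null(truth$modulesMeth)) {
    lab <- network$nets$meth$labels
    tt <- setNames(truth$modulesMeth$module, truth$modulesMeth$probe_id)
    inMod <- names(tt)[tt > 0]
    tp <- sum(lab[inMod] > 0, na.rm = TRUE)
    addRow("module_membership_meth", tp, length(inMod), sum(lab > 0))
  }
  do.call(rbind, rows)
}

#' Human-readable summary of a pipeline run
#'
#' Every number in the report is recomputed from the bundle's emitted
#' tables; there is no report-only arithmetic.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @return character vector of report lines.
#' @export
pipelineReport <- function(bundle) {
  lines <- c("Integrative genotype/methylation/expression analysis", "")
  s <- bundle$assoc$summary
  lines <- c(lines, "Significant methylation-expression associations:")
  for (i in seq_len(NROW(s)))
    lines <- c(lines, sprintf("  %-6s positive %4d  negative %4d  (meth probes %d, expr probes %d)",
      s$relation[i], s$positive[i], s$negative[i], s$meth_probes[i],
      s$expr_probes[i]))
  if (!is.null(bundle$qtl$lociMeth))
    lines <- c(lines, "",
      sprintf("Cis QTL: %d methylation probes with a SNP, %d independent loci; %d expression probes, %d loci",
        bundle$qtl$lociMeth$probesWithSnp, bundle$qtl$lociMeth$totalLoci,
        bundle$qtl$lociExpr$probesWithSnp, bundle$qtl$lociExpr$totalLoci))
  if (!is.null(bundle$enrich)) {
    lines <- c(lines, "", "CpG region enrichment (set, region, fg%, bg%, p):")
    e <- bundle$enrich
    for (i in seq_len(nrow(e)))
      lines <- c(lines, sprintf("  %-13s %-8s %5.1f%% %5.1f%%  p=%.3g %s",
        e$set[i], e$region[i], 100 * e$fg_prop[i], 100 * e$bg_prop[i],
        e$fisher_p[i], e$direction[i]))
  }
  tr <- bundle$causal$triples
  lines <- c(lines, "", "Causal LEO screening:")
  if (NROW(tr)) {
    pm1 <- sum(tr$pass_m1 %in% TRUE); pm2 <- sum(tr$pass_m2 %in% TRUE)
    lines <- c(lines,
      sprintf("  triples tested %d; S->M->E supported %d; S->E->M supported %d; neither %d",
        nrow(tr), pm1, pm2, nrow(tr) - pm1 - pm2))
  } else lines <- c(lines, "  no candidate triples")
  for (nm in names(bundle$preserve)) {
    p <- bundle$preserve[[nm]]
    lines <- c(lines, "", paste0("Module preservation (", nm, "):"))
    for (i in seq_len(nrow(p)))
      lines <- c(lines, sprintf("  module %d (n=%d): Zsummary=%.2f medianRank=%.1f",
        p$module[i], p$size[i], p$Zsummary[i], p$medianRank[i]))
  }
  if (!is.null(bundle$scorecard)) {
    lines <- c(lines, "", "Truth scorecard:")
    sc <- bundle$scorecard
    for (i in seq_len(nrow(sc)))
      lines <- c(lines, sprintf("  %-24s sens=%.2f prec=%.2f (%d/%d called %d)",
        sc$effect_class[i], sc$sensitivity[i], sc$precision[i],
        sc$true_positive[i], sc$n_truth[i], sc$n_called[i]))
  }
  lines
}
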