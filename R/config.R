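#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default.  The
#' defaults follow the study design the package implements: a 500 kb cis
#' window, FDR q 0.05 for cis and Bonferroni alpha 0.05 for trans association
#' tests, MAF filter 0.05 for QTL scanning, LD pruning at r-squared 0.2,
#' LEO support threshold 0.8, inter-array connectivity outlier cut Z.k < -3,
#' and CpG island shores extending 2 kb from an island boundary.
#'
#' @slot cisWindowBp cis window half-width in bp (inclusive boundary).
#' @slot fdrQ Benjamini-Hochberg q threshold for cis tests.
#' @slot alpha family-wise alpha for Bonferroni-corrected trans tests.
#' @slot mafMin minimum minor allele frequency for SNPs entering QTL scans.
#' @slot ldR2 r-squared above which SNPs are pruned as redundant.
#' @slot leoThreshold LEO score above which a causal direction is supported.
#' @slot zkThreshold standardized connectivity below which a sample is an
#'   outlier.
#' @slot shoreBp shore width in bp measured from an island boundary.
#' @slot transMaxPairs cap on enumerated trans pairs (Inf = exhaustive).
#' @slot softPower soft-threshold power for network adjacency; NA = choose by
#'   scale-free fit.
#' @slot networkSign "unsigned" or "signed" adjacency.
#' @slot minModuleSize smallest cluster retained as a module.
#' @slot cutHeightQuantile quantile of dendrogram merge heights at which the
#'   tree is cut.
#' @slot nPerm permutations for module preservation.
#' @slot seed integer RNG seed fanned out to the stochastic stages.
#' @export
setClass("AnalysisConfig", slots = c(
  cisWindowBp = "numeric", fdrQ = "numeric", alpha = "numeric",
  mafMin = "numeric", ldR2 = "numeric", leoThreshold = "numeric",
  zkThreshold = "numeric", shoreBp = "numeric", transMaxPairs = "numeric",
  softPower = "numeric", networkSign = "character",
  minModuleSize = "numeric", cutHeightQuantile = "numeric",
  nPerm = "numeric", seed = "numeric"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  chk <- function(v, lo, hi, name) {
    if (length(v) != 1 || is.na(v) || v < lo || v > hi)
      msg <<- c(msg, sprintf("%s must be a single value in [%g, %g]",
                             name, lo, hi))
  }
  chk(object@cisWindowBp, 0, Inf, "cisWindowBp")
  chk(object@fdrQ, 0, 1, "fdrQ")
  chk(object@alpha, 0, 1, "alpha")
  chk(object@mafMin, 0, 0.5, "mafMin")
  chk(object@ldR2, 0, 1, "ldR2")
  chk(object@leoThreshold, 0, Inf, "leoThreshold")
  chk(object@zkThreshold, -Inf, 0, "zkThreshold")
  chk(object@shoreBp, 0, Inf, "shoreBp")
  if (!is.na(object@softPower))
    chk(object@softPower, 1, Inf, "softPower")
  if (!object@networkSign %in% c("unsigned", "signed"))
    msg <- c(msg, "networkSign must be 'unsigned' or 'signed'")
  chk(object@minModuleSize, 2, Inf, "minModuleSize")
  chk(object@cutHeightQuantile, 0, 1, "cutHeightQuantile")
  chk(object@nPerm, 50, Inf, "nPerm")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param ... named slot overrides, e.g. \code{analysisConfig(fdrQ = 0.1)}.
#' @return An \linkS4class{AnalysisConfig} with defaults where not overridden.
#' @examples
#' cfg <- analysisConfig(seed = 7)
#' cfg@cisWindowBp
#' @export
analysisConfig <- function(...) {
  defaults <- list(
    cisWindowBp = 500000, fdrQ = 0.05, alpha = 0.05, mafMin = 0.05,
    ldR2 = 0.2, leoThreshold = 0.8, zkThreshold = -3, shoreBp = 2000,
    transMaxPairs = Inf, softPower = NA_real_, networkSign = "unsigned",
    minModuleSize = 30, cutHeightQuantile = 0.8, nPerm = 200, seed = 1
  )
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  vals <- modifyList(defaults, args)
  do.call(new, c(list("AnalysisConfig"), vals))
}

#' Read / write an AnalysisConfig as YAML
#'
#' The serialization is lossless: every slot is written and read back
#' unchanged (Inf and NA survive the round trip).
#'
#' @param path YAML file path.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  num <- setdiff(names(vals), "networkSign")
  vals[num] <- lapply(vals[num], function(v) {
    if (identical(v, ".inf")) Inf else if (identical(v, ".na")) NA_real_
    else as.numeric(v)
  })
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param config an \linkS4class{AnalysisConfig}.
#' @export
writeAnalysisConfig <- function(config, path) {
  vals <- configAsList(config)
  vals <- lapply(vals, function(v) {
    if (is.numeric(v) && is.infinite(v)) ".inf"
    else if (is.numeric(v) && is.na(v)) ".na" else v
  })
  yaml::write_yaml(vals, path)
  invisible(path)
}

configAsList <- function(config) {
  nm <- slotNames(config)
  setNames(lapply(nm, function(s) slot(config, s)), nm)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, format(slot(object, s))))
})
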