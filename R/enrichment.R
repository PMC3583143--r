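#' Classify probes relative to CpG islands
#'
#' A probe position (1-based) is \code{island} when inside an island
#' interval, \code{shore} when within \code{shoreBp} bases of the nearest
#' island boundary (inclusive at exactly \code{shoreBp}), and
#' \code{outside} otherwise.  Probes on chromosomes absent from the island
#' set are \code{outside}.
#'
#' @param annotation probe annotation data.frame (probe_id, chrom, pos).
#' @param cgi islands as a \link[GenomicRanges]{GRanges} from
#'   \code{\link{readCgiBed}} (1-based, merged).
#' @param shoreBp shore width in bp (default 2000).
#' @return data.frame with probe_id and region in
#'   \{island, shore, outside\}.
#' @examples
#' cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
#' ann <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
#'                   pos = c(1500, 2500, 4001))
#' classifyRegion(ann, cgi)$region  # island, shore, outside
#' @export
classifyRegion <- function(annotation, cgi, shoreBp = 2000) {
  annotation <- validateAnnotation(annotation)
  probes <- GRanges(annotation$chrom, IRanges(annotation$pos,
                                              annotation$pos))
  region <- rep("outside", nrow(annotation))
  inIsland <- IRanges::overlapsAny(probes, cgi)
  region[inIsland] <- "island"
  # probes on chromosomes absent from the island set get no nearest hit and
  # stay "outside"
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(probes, cgi))
  qi <- S4Vectors::queryHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  # distance() counts positions strictly between the ranges: a probe g >= 1
  # bases past a boundary has distance g - 1, so the inclusive shore
  # condition g <= shoreBp reads d <= shoreBp - 1
  shore <- !inIsland[qi] & d <= shoreBp - 1
  region[qi[shore]] <- "shore"
  data.frame(probe_id = annotation$probe_id, region = region,
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities of tables no more
#' likely than the observed one (the classic convention whose machine floor
#' prints as p < 2.2e-16).  The odds ratio reported is the sample odds ratio
#' \code{(a d) / (b c)} (Inf allowed), not the conditional MLE.
#'
#' @param a,b,c,d nonnegative integer cell counts, laid out as
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return list with \code{oddsRatio} and \code{p}.
#' @examples
#' fisherExact2x2(39, 34, 8718, 18860)$p   # ~1.3e-4
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all-zero margin")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  orat <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
  list(oddsRatio = orat, p = min(p, 1))
}

#' Region enrichment of probe sets against a background universe
#'
#' For each foreground probe set and each region class, tests the 2x2 table
#' \[foreground in class, foreground not in class; background in class,
#' background not in class\] with \code{\link{fisherExact2x2}}.  The
#' background is the full annotated probe universe (e.g. the array
#' manifest), not the analysis subset, and is not foreground-subtracted.
#'
#' @param foregroundSets named list of character vectors of probe ids; each
#'   must be a subset of \code{backgroundProbes}.
#' @param backgroundProbes character vector: the probe universe.
#' @param regionClasses data.frame from \code{\link{classifyRegion}}
#'   covering the background.
#' @return data.frame with one row per set x region: counts, proportions,
#'   odds ratio, fisher_p, direction.
#' @export
enrichmentReport <- function(foregroundSets, backgroundProbes,
                             regionClasses) {
  if (is.null(names(foregroundSets)) || any(names(foregroundSets) == ""))
    stop("foregroundSets must be a named list")
  cls <- setNames(regionClasses$region, regionClasses$probe_id)
  if (anyNA(cls[backgroundProbes]))
    stop("background probes missing region classification")
  bgRegion <- cls[backgroundProbes]
  nBg <- length(backgroundProbes)
  out <- list()
  for (setName in names(foregroundSets)) {
    fg <- foregroundSets[[setName]]
    if (!all(fg %in% backgroundProbes))
      stop("foreground set '", setName, "' is not a subset of the background")
    fgRegion <- cls[fg]
    for (reg in c("island", "shore", "outside")) {
      a <- sum(fgRegion == reg); b <- length(fg) - a
      cc <- sum(bgRegion == reg); dd <- nBg - cc
      ft <- fisherExact2x2(a, b, cc, dd)
      out[[length(out) + 1L]] <- data.frame(
        set = setName, region = reg,
        fg_count = a, fg_total = length(fg),
        bg_count = cc, bg_total = nBg,
        fg_prop = a / length(fg), bg_prop = cc / nBg,
        odds_ratio = ft$oddsRatio, fisher_p = ft$p,
        direction = if (a / length(fg) >= cc / nBg) "enriched" else
          "depleted",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
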