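## Subset a HarmonizedPairs to the instruments not in `rsids`.
.excludePairs <- function(pairs, rsids) {
  tab <- pairs@pairs
  unknown <- setdiff(rsids, tab$rsid)
  if (length(unknown))
    mrWarn(sprintf("excluded rsid(s) not among instruments: %s",
                   paste(unknown, collapse = ", ")),
           "ivwMR_unknown_rsid_warning")
  tab <- tab[!(tab$rsid %in% rsids), , drop = FALSE]
  rownames(tab) <- NULL
  new("HarmonizedPairs",
      exposureTrait = pairs@exposureTrait, outcomeTrait = pairs@outcomeTrait,
      scale = pairs@scale, pairs = tab, log = pairs@log)
}

#' Re-estimate the causal effect with named instruments excluded
#'
#' The exclusion sensitivity analysis: drops the named variants and
#' re-pools the remainder with the same heterogeneity-driven model
#' selection as the baseline. The canonical use is removing a variant
#' suspected of horizontal pleiotropy (e.g. a lipid-associated variant in
#' a vitamin E instrument) and checking whether the estimate moves.
#' Excluding an rsid that is not among the instruments warns but does not
#' fail, so exclusion lists survive instrument-set edits.
#'
#' @param pairs a [HarmonizedPairs].
#' @param excludedRsids character vector of rsids to drop (may be empty,
#'   in which case the result equals the baseline).
#' @param hetAlpha heterogeneity-test level for model selection.
#' @param outcome outcome label for the result.
#' @return a [PooledEstimate] recording the exclusions applied.
#' @export
excludeAndRerun <- function(pairs, excludedRsids, hetAlpha = 0.05,
                            outcome = pairs@outcomeTrait) {
  stopifnot(is(pairs, "HarmonizedPairs"), is.character(excludedRsids))
  sub <- .excludePairs(pairs, excludedRsids)
  if (nInstruments(sub) == 0L)
    mrStop("exclusion removes all instruments", "ivwMR_empty_input_error")
  res <- poolWithModelSelection(sub, hetAlpha = hetAlpha, outcome = outcome)
  res@excludedRsids <- sort(intersect(excludedRsids, pairs@pairs$rsid))
  res
}

#' Leave-one-out sensitivity analysis
#'
#' Generalizes single-variant exclusion: re-pools once per instrument with
#' exactly that instrument left out, and reports the largest absolute shift
#' of the estimate from baseline. A single variant whose exclusion moves
#' the estimate materially is the classic signature of an outlying,
#' possibly pleiotropic instrument.
#'
#' @param pairs a [HarmonizedPairs] with at least two kept instruments.
#' @param hetAlpha heterogeneity-test level for model selection.
#' @param outcome outcome label for the results.
#' @return a [SensitivityReport]; variants are labelled `"-<rsid>"`.
#' @export
leaveOneOut <- function(pairs, hetAlpha = 0.05,
                        outcome = pairs@outcomeTrait) {
  stopifnot(is(pairs, "HarmonizedPairs"))
  kept <- keptPairs(pairs)
  if (nrow(kept) < 2L)
    mrStop("leave-one-out requires at least two instruments",
           "ivwMR_insufficient_instruments_error")
  baseline <- poolWithModelSelection(pairs, hetAlpha = hetAlpha,
                                     outcome = outcome)
  variants <- lapply(kept$rsid, function(rs)
    excludeAndRerun(pairs, rs, hetAlpha = hetAlpha, outcome = outcome))
  names(variants) <- paste0("-", kept$rsid)
  shifts <- vapply(variants, function(v) abs(v@beta - baseline@beta),
                   numeric(1))
  new("SensitivityReport", baseline = baseline, variants = variants,
      maxAbsShift = if (length(shifts)) max(shifts) else 0)
}

#' Tabulate a sensitivity report
#'
#' @param report a [SensitivityReport].
#' @return `data.frame` with the baseline row first, then one row per
#'   exclusion variant (columns as in [as.data.frame.PooledEstimate()],
#'   plus a `label` column).
#' @export
sensitivityTable <- function(report) {
  stopifnot(is(report, "SensitivityReport"))
  rows <- c(list(baseline = report@baseline), report@variants)
  tab <- do.call(rbind, lapply(rows, as.data.frame.PooledEstimate))
  tab <- cbind(label = names(rows), tab)
  rownames(tab) <- NULL
  tab
}
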