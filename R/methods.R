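#' @rdname ivwMR-accessors
#' @aliases estimate,PooledEstimate-method
setMethod("estimate", "PooledEstimate", function(x, ...) x@beta)

#' @rdname ivwMR-accessors
setMethod("stdError", "PooledEstimate", function(x, ...) x@se)

#' @rdname ivwMR-accessors
setMethod("pValue", "PooledEstimate", function(x, ...) x@pvalue)

#' @rdname ivwMR-accessors
setMethod("confInt", "PooledEstimate", function(x, ...)
  c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname ivwMR-accessors
setMethod("modelUsed", "PooledEstimate", function(x, ...) x@model)

#' @rdname ivwMR-accessors
setMethod("hetStats", "PooledEstimate", function(x, ...) x@het)

#' @rdname ivwMR-accessors
setMethod("nInstruments", "PooledEstimate", function(x, ...) x@k)

#' @rdname ivwMR-accessors
setMethod("outcomeScale", "PooledEstimate", function(x, ...) x@scale)

#' @rdname ivwMR-accessors
setMethod("assocTable", "GwasAssociations", function(x, ...) x@table)

#' @rdname ivwMR-accessors
setMethod("provenance", "GwasAssociations", function(x, ...) x@provenance)

#' @rdname ivwMR-accessors
setMethod("nInstruments", "GwasAssociations", function(x, ...)
  nrow(x@table))

#' @rdname ivwMR-accessors
setMethod("keptPairs", "HarmonizedPairs", function(x, ...)
  x@pairs[x@pairs$resolution != "dropped", , drop = FALSE])

#' @rdname ivwMR-accessors
setMethod("droppedPairs", "HarmonizedPairs", function(x, ...)
  x@pairs[x@pairs$resolution == "dropped", , drop = FALSE])

#' @rdname ivwMR-accessors
setMethod("outcomeScale", "HarmonizedPairs", function(x, ...) x@scale)

#' @rdname ivwMR-accessors
setMethod("nInstruments", "HarmonizedPairs", function(x, ...)
  sum(x@pairs$resolution != "dropped"))

setMethod("show", "GwasAssociations", function(object) {
  cat(sprintf("%s with %d variant(s)\n", class(object), nrow(object@table)))
  cat(sprintf("  trait: %s [%s%s]\n", object@trait, object@scale,
              if (nzchar(object@unitLabel))
                paste0(", ", object@unitLabel) else ""))
  if (is(object, "InstrumentSet"))
    cat(sprintf("  selection threshold: p < %g\n", object@pThreshold))
  if (nrow(object@table)) {
    print(utils::head(object@table, 5L), row.names = FALSE)
    if (nrow(object@table) > 5L)
      cat(sprintf("  ... and %d more\n", nrow(object@table) - 5L))
  }
  invisible(NULL)
})

setMethod("show", "HarmonizedPairs", function(object) {
  kept <- sum(object@pairs$resolution != "dropped")
  cat(sprintf("HarmonizedPairs: %s -> %s (%s scale)\n",
              object@exposureTrait, object@outcomeTrait, object@scale))
  cat(sprintf("  %d instrument(s) kept, %d dropped\n",
              kept, nrow(object@pairs) - kept))
  if (length(object@log))
    cat("  decisions:", paste(sprintf("%s=%d", names(object@log), object@log),
                              collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "HeterogeneityStats", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df (p = %s); I2 = %.1f%%, tau2 = %.4g\n",
              object@q, as.integer(object@df),
              ifelse(is.na(object@pHet), "NA", sprintf("%.3g", object@pHet)),
              100 * object@i2, object@tau2))
  invisible(NULL)
})

setMethod("show", "PooledEstimate", function(object) {
  cat(sprintf("PooledEstimate for %s (%s-effects IVW, k = %d)\n",
              object@outcome, object@model, object@k))
  if (length(object@excludedRsids))
    cat("  excluded:", paste(object@excludedRsids, collapse = ", "), "\n")
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
  if (object@scale == "log_odds") {
    or <- toOddsRatio(object)
    cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f] per unit exposure\n",
                or$or, or$ciLow, or$ciHigh))
  }
  if (object@k >= 2L) show(object@het)
  invisible(NULL)
})

setMethod("show", "InstrumentStrength", function(object) {
  cat(sprintf("Instrument strength: F = %.2f (R2 = %.3g%%, n = %d, k = %d)\n",
              object@f, 100 * object@r2, as.integer(object@n), object@k))
  invisible(NULL)
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("SensitivityReport: baseline k = %d, %d exclusion variant(s)\n",
              object@baseline@k, length(object@variants)))
  cat(sprintf("  max |beta shift| = %.4g\n", object@maxAbsShift))
  invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d variant(s), theta = %g, seed = %d\n",
              nrow(object@snps), object@trueEffect, object@seed))
  if (object@outcomeKind == "binary")
    cat(sprintf("  binary outcome: %d cases / %d controls\n",
                as.integer(object@nCases), as.integer(object@nControls)))
  else
    cat(sprintf("  continuous outcome: n = %d\n", as.integer(object@nOutcome)))
  if (length(object@pleiotropy))
    cat("  pleiotropy:", paste(sprintf("%s=%g", names(object@pleiotropy),
                                       object@pleiotropy), collapse = ", "),
        "\n")
  invisible(NULL)
})

#' Coerce a pooled estimate (or list of them) to a one-row data.frame
#'
#' @param x a [PooledEstimate].
#' @param row.names,optional ignored, for generic consistency.
#' @param ... ignored.
#' @return `data.frame` with outcome, k, model, scale, estimate, SE, CI,
#'   p-value and heterogeneity columns.
#' @export
as.data.frame.PooledEstimate <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    outcome = x@outcome,
    k = x@k,
    model = x@model,
    scale = x@scale,
    beta = x@beta,
    se = x@se,
    ci_low = x@ciLow,
    ci_high = x@ciHigh,
    pvalue = x@pvalue,
    q = x@het@q,
    het_df = x@het@df,
    het_p = x@het@pHet,
    i2 = x@het@i2,
    tau2 = x@het@tau2,
    excluded = paste(x@excludedRsids, collapse = ","),
    stringsAsFactors = FALSE
  )
}

setMethod("as.data.frame", "PooledEstimate", as.data.frame.PooledEstimate)
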