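#' RunConfig: full parameterization of an analysis run
#'
#' @slot exposurePath path to the exposure summary-statistic file.
#' @slot exposureColumnMap named character vector (or preset name) for the
#'   exposure file layout.
#' @slot exposureUnit unit label of the exposure beta (e.g. `"mg/L"`).
#' @slot outcomes named list; each element a list with `path`, optional
#'   `columnMap` (named vector or preset name, default `"default"`) and
#'   `scale` (`"log_odds"` or `"continuous"`).
#' @slot pThreshold instrument-selection p-value threshold.
#' @slot hetAlpha heterogeneity-test level for model selection.
#' @slot palindromicPolicy `"infer_by_eaf"` or `"drop"`.
#' @slot eafAmbiguityBand half-width of the EAF ambiguity band.
#' @slot exclusions named list of rsid character vectors; one sensitivity
#'   table is produced per named set.
#' @slot leaveOneOut logical; also run the leave-one-out analysis.
#' @slot outputDir directory for result tables (`NA` = no files written).
#' @slot firstStageN exposure GWAS sample size for the F-statistic block.
#' @slot phenotypeVariance exposure phenotype variance for R^2 (`NA`
#'   disables the instrument-strength block).
#' @export
setClass("RunConfig",
  representation(
    exposurePath = "character", exposureColumnMap = "character",
    exposureUnit = "character", outcomes = "list",
    pThreshold = "numeric", hetAlpha = "numeric",
    palindromicPolicy = "character", eafAmbiguityBand = "numeric",
    exclusions = "list", leaveOneOut = "logical",
    outputDir = "character", firstStageN = "numeric",
    phenotypeVariance = "numeric"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@outcomes) == 0L)
    msg <- c(msg, "at least one outcome is required")
  if (is.null(names(object@outcomes)) || any(!nzchar(names(object@outcomes))))
    msg <- c(msg, "outcomes must be named")
  for (nm in names(object@outcomes)) {
    o <- object@outcomes[[nm]]
    if (is.null(o$path))
      msg <- c(msg, sprintf("outcome '%s': missing path", nm))
    if (!is.null(o$scale) && !o$scale %in% c("continuous", "log_odds"))
      msg <- c(msg, sprintf("outcome '%s': bad scale", nm))
  }
  if (!object@palindromicPolicy %in% c("infer_by_eaf", "drop"))
    msg <- c(msg, "palindromicPolicy must be 'infer_by_eaf' or 'drop'")
  if (length(msg)) msg else TRUE
})

#' Build a RunConfig
#'
#' @param exposurePath path to the exposure summary statistics.
#' @param outcomes named list of outcome descriptors, each a list with
#'   `path` and optionally `columnMap` (preset name or named vector,
#'   default `"default"`) and `scale` (default `"log_odds"`).
#' @param exposureColumnMap preset name or named vector for the exposure
#'   file (default `"default"`).
#' @param exposureUnit unit label for the exposure beta.
#' @param pThreshold,hetAlpha,palindromicPolicy,eafAmbiguityBand analysis
#'   parameters (see [selectInstruments()], [poolWithModelSelection()],
#'   [harmonize()]).
#' @param exclusions named list of rsid vectors for sensitivity re-runs.
#' @param leaveOneOut also run [leaveOneOut()] per outcome.
#' @param outputDir where to write result tables; `NA` writes nothing.
#' @param firstStageN,phenotypeVariance inputs for the instrument-strength
#'   block; leave `phenotypeVariance = NA` to skip it.
#' @return a validated [RunConfig].
#' @export
runConfig <- function(exposurePath, outcomes,
                      exposureColumnMap = "default",
                      exposureUnit = "",
                      pThreshold = 5e-8, hetAlpha = 0.05,
                      palindromicPolicy = "infer_by_eaf",
                      eafAmbiguityBand = 0.08,
                      exclusions = list(), leaveOneOut = FALSE,
                      outputDir = NA_character_,
                      firstStageN = NA_real_,
                      phenotypeVariance = NA_real_) {
  tryCatch(
    new("RunConfig",
        exposurePath = exposurePath,
        exposureColumnMap = exposureColumnMap,
        exposureUnit = exposureUnit,
        outcomes = outcomes, pThreshold = pThreshold,
        hetAlpha = hetAlpha, palindromicPolicy = palindromicPolicy,
        eafAmbiguityBand = eafAmbiguityBand, exclusions = exclusions,
        leaveOneOut = leaveOneOut, outputDir = outputDir,
        firstStageN = firstStageN,
        phenotypeVariance = phenotypeVariance),
    error = function(e)
      mrStop(paste("invalid RunConfig:", conditionMessage(e)),
             "ivwMR_config_error"))
}

#' Read a RunConfig from a YAML file
#'
#' The file mirrors [runConfig()]'s arguments; `outcomes` is a mapping
#' from outcome name to `path` / `columnMap` / `scale`, and `exclusions`
#' a mapping from label to a list of rsids. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path path to the YAML file.
#' @return a validated [RunConfig].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    mrStop(sprintf("config file not found: %s", path), "ivwMR_config_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$exposure) || is.null(y$exposure$path) || is.null(y$outcomes))
    mrStop("config must define exposure.path and outcomes",
           "ivwMR_config_error")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  outcomes <- lapply(y$outcomes, function(o) {
    o$path <- resolve(o$path)
    o
  })
  exclusions <- lapply(y$exclusions %||% list(), unlist)
  runConfig(
    exposurePath = resolve(y$exposure$path),
    exposureColumnMap = y$exposure$columnMap %||% "default",
    exposureUnit = y$exposure$unit %||% "",
    outcomes = outcomes,
    pThreshold = y$p_threshold %||% 5e-8,
    hetAlpha = y$het_alpha %||% 0.05,
    palindromicPolicy = y$palindromic_policy %||% "infer_by_eaf",
    eafAmbiguityBand = y$eaf_ambiguity_band %||% 0.08,
    exclusions = exclusions,
    leaveOneOut = isTRUE(y$leave_one_out),
    outputDir = if (!is.null(y$output_dir)) resolve(y$output_dir)
                else NA_character_,
    firstStageN = y$first_stage_n %||% NA_real_,
    phenotypeVariance = y$phenotype_variance %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolveMap <- function(m) {
  if (is.null(m)) return(columnPreset("default"))
  if (is.character(m) && is.null(names(m)) && length(m) == 1L)
    return(columnPreset(m))
  m <- unlist(m)
  if (is.null(names(m)))
    mrStop("columnMap must be a preset name or a named mapping",
           "ivwMR_config_error")
  m
}

#' Run the full two-sample MR analysis
#'
#' Orchestrates the pipeline for every configured outcome: read the
#' exposure table, select instruments, then per outcome read, harmonize,
#' pool with model selection, convert log-odds estimates to odds ratios,
#' and run the configured exclusion sets and optional leave-one-out. An
#' instrument-strength block (R^2 and F) is computed when
#' `phenotypeVariance` and `firstStageN` are supplied. A failing outcome is
#' reported with its stage and message; the remaining outcomes still
#' complete. If `outputDir` is set, the main results table, one
#' sensitivity table per exclusion label, the harmonization log and the
#' strength block are written as tab-delimited files.
#'
#' @param config a [RunConfig] or path to a YAML config file.
#' @return (invisibly if files are written) a list with elements
#'   `results` (list of [PooledEstimate] per outcome), `table` (main
#'   results `data.frame`), `sensitivity` (per exclusion label, a
#'   `data.frame`), `loo` (per outcome, a [SensitivityReport]),
#'   `strength` ([InstrumentStrength] or `NULL`), `harmonization`
#'   (per outcome decision counts), `errors` (named character).
#' @export
runAnalysis <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(is(config, "RunConfig"))

  exposure <- readAssociationTable(
    config@exposurePath, columnMap = .resolveMap(config@exposureColumnMap),
    traitUnits = "continuous", trait = "exposure",
    unitLabel = config@exposureUnit)
  instruments <- selectInstruments(exposure, pThreshold = config@pThreshold)
  message(sprintf("ivwMR: %d instrument(s) selected at p < %g from %s",
                  nInstruments(instruments), config@pThreshold,
                  config@exposurePath))

  strength <- NULL
  if (is.finite(config@phenotypeVariance) && is.finite(config@firstStageN)) {
    strength <- tryCatch(
      fStatistic(instrumentR2(instruments, config@phenotypeVariance),
                 n = config@firstStageN, k = nInstruments(instruments)),
      ivwMR_error = function(e) {
        message("ivwMR: instrument-strength block skipped: ",
                conditionMessage(e))
        NULL
      })
  }

  results <- list(); sens <- list(); loo <- list()
  harmLog <- list(); errors <- character()

  for (nm in names(config@outcomes)) {
    oc <- config@outcomes[[nm]]
    stage <- "read"
    res <- tryCatch({
      outTab <- readAssociationTable(
        oc$path, columnMap = .resolveMap(oc$columnMap),
        traitUnits = oc$scale %||% "log_odds", trait = nm)
      stage <- "harmonize"
      pairs <- harmonize(instruments, outTab,
                         palindromicPolicy = config@palindromicPolicy,
                         eafAmbiguityBand = config@eafAmbiguityBand)
      harmLog[[nm]] <- pairs@log
      if (nInstruments(pairs) == 0L)
        mrStop("no instruments survive harmonization",
               "ivwMR_empty_instruments_error")
      stage <- "pool"
      pooled <- poolWithModelSelection(pairs, hetAlpha = config@hetAlpha,
                                       outcome = nm)
      stage <- "sensitivity"
      for (lab in names(config@exclusions)) {
        row <- excludeAndRerun(pairs, config@exclusions[[lab]],
                               hetAlpha = config@hetAlpha, outcome = nm)
        sens[[lab]] <- rbind(sens[[lab]],
                             as.data.frame.PooledEstimate(row))
      }
      if (config@leaveOneOut && nInstruments(pairs) >= 2L)
        loo[[nm]] <- leaveOneOut(pairs, hetAlpha = config@hetAlpha,
                                 outcome = nm)
      pooled
    }, error = function(e) {
      errors[[nm]] <<- sprintf("[%s] %s", stage, conditionMessage(e))
      message(sprintf("ivwMR: outcome '%s' failed at %s: %s",
                      nm, stage, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) results[[nm]] <- res
  }

  mainTable <- if (length(results))
    do.call(rbind, lapply(results, as.data.frame.PooledEstimate))
  else NULL
  report <- list(results = results, table = mainTable,
                 presentation = if (length(results))
                   presentationTable(results) else NULL,
                 sensitivity = sens, loo = loo, strength = strength,
                 harmonization = harmLog, errors = errors,
                 instruments = instruments)

  if (!is.na(config@outputDir)) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    writeResults(results, file.path(config@outputDir, "results_main.tsv"))
    utils::write.table(report$presentation,
                       file.path(config@outputDir, "results_display.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lab in names(sens))
      utils::write.table(sens[[lab]],
                         file.path(config@outputDir,
                                   sprintf("sensitivity_%s.tsv", lab)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(harmLog)) {
      hl <- do.call(rbind, lapply(harmLog, function(x)
        as.data.frame(as.list(x))))
      hl <- cbind(outcome = names(harmLog), hl)
      utils::write.table(hl,
                         file.path(config@outputDir, "harmonization_log.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(strength))
      utils::write.table(
        data.frame(r2 = strength@r2, n = strength@n, k = strength@k,
                   f = strength@f),
        file.path(config@outputDir, "instrument_strength.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

.formatP <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3g", p))

#' Presentation table of pooled results
#'
#' Formats pooled estimates the way MR papers report them: odds ratios (to
#' 3 decimals) with 95% CI for log-odds outcomes, betas (3 decimals) for
#' continuous ones, p-values shown as `<0.001` below 0.001, the selected
#' model, I-squared as a percentage and the heterogeneity p. Full
#' precision lives in [writeResults()] output, not here.
#'
#' @param results list of [PooledEstimate].
#' @return `data.frame` ready for printing.
#' @export
presentationTable <- function(results) {
  if (is(results, "PooledEstimate")) results <- list(results)
  rows <- lapply(results, function(x) {
    lo <- x@scale == "log_odds"
    est <- if (lo) toOddsRatio(x) else NULL
    data.frame(
      outcome = x@outcome, k = x@k,
      measure = if (lo) "OR" else "beta",
      estimate = sprintf("%.3f", if (lo) est$or else x@beta),
      ci95 = if (lo) sprintf("%.3f to %.3f", est$ciLow, est$ciHigh)
             else sprintf("%.3f to %.3f", x@ciLow, x@ciHigh),
      pvalue = .formatP(x@pvalue),
      model = x@model,
      i2 = if (x@k >= 2L) sprintf("%.0f%%", 100 * x@het@i2) else "",
      het_p = if (x@k >= 2L && !is.na(x@het@pHet)) .formatP(x@het@pHet)
              else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
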