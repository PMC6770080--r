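#' Built-in column-map presets for common summary-statistic layouts
#'
#' A column map is a named character vector translating the canonical field
#' names (`rsid`, `chromosome`, `effect_allele`, `other_allele`, `beta`,
#' `se`, `eaf`, `pvalue`, `n`) to the headers of a particular file layout.
#' Two presets ship with the package: `"default"`, the layout written by
#' [writeFixture()] (canonical names as headers), and `"instrument_table"`,
#' the layout of the bundled serum vitamin E instrument file under
#' `inst/extdata` (headers `SNP`, `Chromosome`, `EffectAllele`, ...).
#'
#' @param name preset name.
#' @return named character vector usable as `columnMap`.
#' @examples
#' columnPreset("default")
#' @export
columnPreset <- function(name = c("default", "instrument_table")) {
  name <- match.arg(name)
  switch(name,
    default = c(
      rsid = "rsid", chromosome = "chromosome",
      effect_allele = "effect_allele", other_allele = "other_allele",
      beta = "beta", se = "se", eaf = "eaf", pvalue = "pvalue", n = "n"
    ),
    instrument_table = c(
      rsid = "SNP", chromosome = "Chromosome",
      effect_allele = "EffectAllele", other_allele = "OtherAllele",
      beta = "Beta", se = "SE", eaf = "EAF", pvalue = "Pvalue", n = "N"
    )
  )
}

## Assemble a GwasAssociations from a raw data.frame, dropping (and
## counting) rows that violate the per-record invariants.
.makeAssociations <- function(raw, trait, scale, unitLabel, source) {
  for (col in .ASSOC_COLS)
    if (is.null(raw[[col]])) raw[[col]] <- NA
  raw <- raw[.ASSOC_COLS]
  raw$rsid <- as.character(raw$rsid)
  raw$chromosome <- as.character(raw$chromosome)
  raw$effect_allele <- toupper(trimws(as.character(raw$effect_allele)))
  raw$other_allele <- toupper(trimws(as.character(raw$other_allele)))
  for (col in c("beta", "se", "eaf", "pvalue", "n"))
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))

  ok <- !is.na(raw$rsid) & nzchar(raw$rsid) &
    raw$effect_allele %in% .VALID_ALLELES &
    raw$other_allele %in% .VALID_ALLELES &
    raw$effect_allele != raw$other_allele &
    is.finite(raw$beta) &
    is.finite(raw$se) & raw$se > 0 &
    (is.na(raw$eaf) | (raw$eaf >= 0 & raw$eaf <= 1)) &
    (is.na(raw$pvalue) | (raw$pvalue > 0 & raw$pvalue <= 1))

  kept <- raw[ok, , drop = FALSE]
  rownames(kept) <- NULL
  new("GwasAssociations",
      trait = trait, scale = scale, unitLabel = unitLabel, table = kept,
      provenance = list(source = source, n_read = nrow(raw),
                        n_kept = nrow(kept), n_skipped = sum(!ok)))
}

#' Read a GWAS summary-statistic table
#'
#' Parses a tab- or whitespace-delimited text file with a header row into a
#' [GwasAssociations] object. Parsing is header-driven: `columnMap` names
#' the file's headers for each canonical field, so column order in the file
#' is irrelevant. Rows failing record validation (non-positive SE, invalid
#' alleles, out-of-range EAF or p) are skipped and counted in the
#' provenance, mirroring how consortium files with odd rows are handled in
#' practice.
#'
#' @param path path to the file.
#' @param columnMap named character vector mapping canonical field names to
#'   file headers (see [columnPreset()]), or a preset name. Must cover at
#'   least `rsid`, `effect_allele`, `other_allele`, `beta`, `se`.
#' @param traitUnits `"continuous"` or `"log_odds"` — the scale of `beta`.
#' @param trait trait name stored with the object.
#' @param unitLabel unit label for `beta` (e.g. `"mg/L"`).
#' @return a [GwasAssociations]; provenance records path and row counts.
#' @export
readAssociationTable <- function(path,
                                 columnMap = columnPreset("default"),
                                 traitUnits = c("continuous", "log_odds"),
                                 trait = basename(path),
                                 unitLabel = "") {
  traitUnits <- match.arg(traitUnits)
  if (is.character(columnMap) && is.null(names(columnMap)) &&
      length(columnMap) == 1L)
    columnMap <- columnPreset(columnMap)
  if (!file.exists(path))
    mrStop(sprintf("file not found: %s", path), "ivwMR_input_error")

  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(columnMap))
  if (length(missing))
    mrStop(sprintf("columnMap must map: %s", paste(missing, collapse = ", ")),
           "ivwMR_config_error")

  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "", quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e)
      mrStop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
             "ivwMR_input_error"))
  if (nrow(raw) == 0L)
    mrStop(sprintf("empty file: %s", path), "ivwMR_input_error")

  absent <- columnMap[!(columnMap %in% names(raw))]
  absent <- absent[names(absent) %in% required]
  if (length(absent))
    mrStop(sprintf("mapped column(s) not in file header: %s",
                   paste(sprintf("%s -> %s", names(absent), absent),
                         collapse = ", ")),
           "ivwMR_config_error")

  tab <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in .ASSOC_COLS) {
    header <- columnMap[[field]]
    tab[[field]] <- if (!is.null(header) && header %in% names(raw))
      raw[[header]] else NA
  }
  .makeAssociations(tab, trait = trait, scale = traitUnits,
                    unitLabel = unitLabel, source = path)
}

#' Select genome-wide-significant instruments
#'
#' Retains exactly the associations with `pvalue < pThreshold` (strict
#' inequality) and returns them as an [InstrumentSet], sorted by rsid so
#' downstream results never depend on input order.
#'
#' @param associations a [GwasAssociations] for the exposure.
#' @param pThreshold significance threshold in (0, 1); the conventional
#'   genome-wide level `5e-8` by default.
#' @return an [InstrumentSet] recording the threshold used.
#' @export
selectInstruments <- function(associations, pThreshold = 5e-8) {
  stopifnot(is(associations, "GwasAssociations"))
  if (!is.numeric(pThreshold) || length(pThreshold) != 1L ||
      !is.finite(pThreshold) || pThreshold <= 0 || pThreshold >= 1)
    mrStop("pThreshold must be a single value in (0, 1)", "ivwMR_config_error")
  tab <- associations@table
  keep <- !is.na(tab$pvalue) & tab$pvalue < pThreshold
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L)
    mrStop(sprintf("no association passes p < %g; cannot build instruments",
                   pThreshold),
           "ivwMR_empty_instruments_error")
  if (anyDuplicated(tab$rsid))
    mrStop("duplicate rsids among selected instruments", "ivwMR_input_error")
  tab <- tab[order(tab$rsid), , drop = FALSE]
  rownames(tab) <- NULL
  new("InstrumentSet",
      trait = associations@trait, scale = associations@scale,
      unitLabel = associations@unitLabel, table = tab,
      provenance = c(associations@provenance,
                     list(p_threshold = pThreshold,
                          n_selected = nrow(tab))),
      pThreshold = pThreshold)
}

#' Write and read pooled-result tables
#'
#' `writeResults()` serializes a list of [PooledEstimate] objects to a
#' tab-delimited table (one row per outcome: estimate, SE, 95% CI, p-value,
#' model, I-squared, heterogeneity p, ...), at full double precision so the
#' table round-trips through `readResults()` without loss to well beyond 10
#' significant digits. An empty list yields a header-only file.
#'
#' @param results list of [PooledEstimate] (a single object is accepted).
#' @param path output file path.
#' @return `writeResults()` returns `path` invisibly; `readResults()`
#'   returns the table as a `data.frame`.
#' @export
writeResults <- function(results, path) {
  if (is(results, "PooledEstimate")) results <- list(results)
  if (!all(vapply(results, is, logical(1), "PooledEstimate")))
    mrStop("results must be PooledEstimate objects", "ivwMR_config_error")
  tab <- if (length(results))
    do.call(rbind, lapply(results, as.data.frame.PooledEstimate))
  else {
    proto <- as.data.frame.PooledEstimate(
      new("PooledEstimate", outcome = "x", beta = 0, se = 1, ciLow = -2,
          ciHigh = 2, pvalue = 1, model = "fixed",
          het = new("HeterogeneityStats"), k = 1L, scale = "continuous"))
    proto[0, , drop = FALSE]
  }
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) format(x, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    mrStop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
           "ivwMR_io_error")
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  if (!file.exists(path))
    mrStop(sprintf("file not found: %s", path), "ivwMR_input_error")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(outcome = "character",
                                   model = "character",
                                   scale = "character",
                                   excluded = "character"))
}
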