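# Fixtures are built in code: small association tables in the canonical
# layout, plus direct constructors for harmonized pairs so estimator tests
# need not route through file IO.

# The published three-variant serum vitamin E instrument panel.
vitaminEInstrumentTable <- function() {
  data.frame(
    rsid = c("rs11057830", "rs2108622", "rs964184"),
    chromosome = c("12", "19", "11"),
    effect_allele = c("A", "T", "G"),
    other_allele = c("G", "C", "C"),
    beta = c(0.03, 0.03, 0.04),
    se = c(0.01, 0.01, 0.01),
    eaf = c(0.15, 0.21, 0.15),
    pvalue = c(8.2e-9, 1.4e-10, 7.8e-12),
    n = 7781,
    stringsAsFactors = FALSE
  )
}

makeAssociations <- function(tab, scale = "continuous", trait = "trait") {
  full <- data.frame(
    rsid = tab$rsid,
    chromosome = if (is.null(tab$chromosome)) NA_character_ else tab$chromosome,
    effect_allele = tab$effect_allele,
    other_allele = tab$other_allele,
    beta = tab$beta,
    se = tab$se,
    eaf = if (is.null(tab$eaf)) NA_real_ else tab$eaf,
    pvalue = if (is.null(tab$pvalue)) NA_real_ else tab$pvalue,
    n = if (is.null(tab$n)) NA_real_ else tab$n,
    stringsAsFactors = FALSE
  )
  new("GwasAssociations", trait = trait, scale = scale, unitLabel = "",
      table = full,
      provenance = list(source = "in-memory", n_read = nrow(full),
                        n_kept = nrow(full), n_skipped = 0L))
}

# Directly assemble a HarmonizedPairs from (E, D, sigma_D) triples.
makePairs <- function(E, D, sD, rsid = sprintf("rs%03d", seq_along(E)),
                      scale = "continuous") {
  tab <- data.frame(
    rsid = rsid, effect_allele = "A", other_allele = "G",
    beta_exposure = E, se_exposure = 0.01, eaf_exposure = 0.2,
    beta_outcome = D, se_outcome = sD, eaf_outcome = 0.2,
    flip_applied = FALSE, palindromic = FALSE, resolution = "direct",
    reason = NA_character_, stringsAsFactors = FALSE
  )
  new("HarmonizedPairs", exposureTrait = "exposure", outcomeTrait = "outcome",
      scale = scale, pairs = tab, log = integer())
}

writeAssocFile <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# One full simulated replicate: simulate, select (loose threshold: the
# generator's p-values are exact, so published-table rounding artefacts do
# not apply), harmonize, pool.
simulateAndPool <- function(seed, trueEffect, pleiotropy = numeric(),
                            hetAlpha = 0.05, ...) {
  cfg <- simulationConfig(seed = seed, trueEffect = trueEffect,
                          pleiotropy = pleiotropy, ...)
  st <- simulateStudy(cfg)
  prs <- harmonize(selectInstruments(st$exposure, pThreshold = 0.999999),
                   st$outcome)
  poolWithModelSelection(prs, hetAlpha = hetAlpha)
}
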