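#' @import methods
NULL

## Condition helper: all package errors carry a subclass so callers and the
## CLI can distinguish configuration problems from data problems.
mrStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ivwMR_error")))
}

mrWarn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "ivwMR_warning")))
}

.VALID_ALLELES <- c("A", "C", "G", "T")

.ASSOC_COLS <- c("rsid", "chromosome", "effect_allele", "other_allele",
                 "beta", "se", "eaf", "pvalue", "n")

## Validate a per-variant association table (one row per SNP).
## Returns a character vector of problems, zero-length if clean.
.validateAssocTable <- function(tab) {
  msg <- character()
  missing <- setdiff(.ASSOC_COLS, names(tab))
  if (length(missing))
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  if (nrow(tab) == 0L) return(msg)
  if (any(is.na(tab$rsid) | !nzchar(tab$rsid)))
    msg <- c(msg, "rsid must be non-empty")
  bad <- !(tab$effect_allele %in% .VALID_ALLELES) |
         !(tab$other_allele %in% .VALID_ALLELES)
  if (any(bad))
    msg <- c(msg, "alleles must be single uppercase A/C/G/T")
  if (any(tab$effect_allele == tab$other_allele))
    msg <- c(msg, "effect and other allele must differ")
  if (any(!is.finite(tab$beta)))
    msg <- c(msg, "beta must be finite")
  if (any(!is.finite(tab$se) | tab$se <= 0))
    msg <- c(msg, "se must be finite and > 0")
  eaf <- tab$eaf[!is.na(tab$eaf)]
  if (any(eaf < 0 | eaf > 1))
    msg <- c(msg, "eaf must lie in [0, 1]")
  p <- tab$pvalue[!is.na(tab$pvalue)]
  if (any(p <= 0 | p > 1))
    msg <- c(msg, "pvalue must lie in (0, 1]")
  msg
}

#' GwasAssociations: per-variant summary associations with one trait
#'
#' Container for GWAS summary statistics of a single trait: one row per
#' variant with alleles, per-effect-allele beta, its standard error,
#' effect-allele frequency, p-value and sample size. `eaf`, `pvalue`,
#' `chromosome` and `n` may be `NA` when the source file lacks them.
#'
#' @slot trait trait name, e.g. `"vitamin E"` or `"CAD"`.
#' @slot scale `"continuous"` (betas in trait units or SD) or `"log_odds"`
#'   (betas are log odds ratios from a case-control study).
#' @slot unitLabel unit of `beta`, e.g. `"mg/L"`, `"SD"`, `"log(OR)"`.
#' @slot table `data.frame` with columns `rsid`, `chromosome`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pvalue`, `n`.
#' @slot provenance list with at least `source`, `n_read`, `n_kept`,
#'   `n_skipped` describing where the rows came from.
#' @export
setClass("GwasAssociations",
  representation(
    trait = "character",
    scale = "character",
    unitLabel = "character",
    table = "data.frame",
    provenance = "list"
  ),
  prototype(
    trait = NA_character_, scale = "continuous", unitLabel = "",
    table = data.frame(), provenance = list()
  )
)

setValidity("GwasAssociations", function(object) {
  if (!object@scale %in% c("continuous", "log_odds"))
    return("scale must be 'continuous' or 'log_odds'")
  msg <- .validateAssocTable(object@table)
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: genome-wide-significant instruments for an exposure
#'
#' A [GwasAssociations] restricted to variants passing the instrument
#' selection p-value threshold (strict `p < threshold`), with unique rsids
#' in deterministic rsid-sorted order.
#'
#' @slot pThreshold the selection threshold the set was built with.
#' @export
setClass("InstrumentSet",
  contains = "GwasAssociations",
  representation(pThreshold = "numeric"),
  prototype(pThreshold = 5e-8)
)

setValidity("InstrumentSet", function(object) {
  tab <- object@table
  msg <- character()
  if (anyDuplicated(tab$rsid))
    msg <- c(msg, "instrument rsids must be unique")
  if (is.unsorted(tab$rsid))
    msg <- c(msg, "instruments must be sorted by rsid")
  if (length(object@pThreshold) != 1L || !is.finite(object@pThreshold) ||
      object@pThreshold <= 0 || object@pThreshold >= 1)
    msg <- c(msg, "pThreshold must be a single value in (0, 1)")
  else if (nrow(tab) && any(is.na(tab$pvalue) | tab$pvalue >= object@pThreshold))
    msg <- c(msg, "all instruments must have pvalue < pThreshold")
  if (length(msg)) msg else TRUE
})

.PAIR_COLS <- c("rsid", "effect_allele", "other_allele",
                "beta_exposure", "se_exposure", "eaf_exposure",
                "beta_outcome", "se_outcome", "eaf_outcome",
                "flip_applied", "palindromic", "resolution")

.RESOLUTIONS <- c("direct", "flipped", "eaf_inferred", "dropped")

#' HarmonizedPairs: exposure/outcome associations aligned to one allele
#'
#' One row per exposure instrument, pairing its exposure association with
#' the outcome association expressed for the same effect allele. Rows with
#' `resolution == "dropped"` (variant absent from the outcome study,
#' ambiguous palindrome, invalid record) are retained for reporting but
#' excluded from estimation; [keptPairs()] returns the usable rows.
#'
#' @slot exposureTrait,outcomeTrait trait names carried through from inputs.
#' @slot scale outcome scale, `"continuous"` or `"log_odds"`.
#' @slot pairs `data.frame`, one row per instrument, with exposure and
#'   outcome beta/se/eaf, `flip_applied` (outcome beta sign was flipped),
#'   `palindromic` (A/T or G/C variant) and `resolution` (one of
#'   `direct`, `flipped`, `eaf_inferred`, `dropped`).
#' @slot log named integer counts of harmonization decisions.
#' @export
setClass("HarmonizedPairs",
  representation(
    exposureTrait = "character",
    outcomeTrait = "character",
    scale = "character",
    pairs = "data.frame",
    log = "integer"
  ),
  prototype(
    exposureTrait = NA_character_, outcomeTrait = NA_character_,
    scale = "continuous", pairs = data.frame(), log = integer()
  )
)

setValidity("HarmonizedPairs", function(object) {
  tab <- object@pairs
  missing <- setdiff(.PAIR_COLS, names(tab))
  if (length(missing))
    return(sprintf("missing pair columns: %s", paste(missing, collapse = ", ")))
  if (nrow(tab) && !all(tab$resolution %in% .RESOLUTIONS))
    return("resolution must be direct/flipped/eaf_inferred/dropped")
  kept <- tab[tab$resolution != "dropped", , drop = FALSE]
  if (nrow(kept) && any(!is.finite(kept$se_outcome) | kept$se_outcome <= 0))
    return("kept pairs must have finite positive outcome se")
  TRUE
})

#' HeterogeneityStats: Cochran's Q, I-squared and DerSimonian-Laird tau^2
#'
#' Dispersion of per-variant Wald ratios about the fixed-effect pooled
#' estimate, computed with the fixed IVW weights. `pHet` is `NA` when
#' `df == 0` (a single instrument carries no heterogeneity information).
#'
#' @slot q Cochran's Q statistic (>= 0).
#' @slot df degrees of freedom, k - 1.
#' @slot pHet upper-tail chi-square p-value of `q` at `df`; `NA` if df = 0.
#' @slot i2 heterogeneity fraction `max(0, (Q - df)/Q)` in \[0, 1).
#' @slot tau2 DerSimonian-Laird between-variant variance (>= 0).
#' @export
setClass("HeterogeneityStats",
  representation(q = "numeric", df = "numeric", pHet = "numeric",
                 i2 = "numeric", tau2 = "numeric"),
  prototype(q = 0, df = 0, pHet = NA_real_, i2 = 0, tau2 = 0)
)

setValidity("HeterogeneityStats", function(object) {
  msg <- character()
  if (!is.finite(object@q) || object@q < 0) msg <- c(msg, "q must be >= 0")
  if (object@i2 < 0 || object@i2 >= 1) msg <- c(msg, "i2 must lie in [0, 1)")
  if (object@tau2 < 0) msg <- c(msg, "tau2 must be >= 0")
  if (object@q == 0 && (object@i2 != 0 || object@tau2 != 0))
    msg <- c(msg, "q == 0 implies i2 == 0 and tau2 == 0")
  if (length(msg)) msg else TRUE
})

#' PooledEstimate: inverse-variance weighted causal-effect estimate
#'
#' The pooled causal effect of a one-unit exposure increase on the outcome,
#' with Wald 95% confidence interval and two-sided normal p-value, plus the
#' model used (fixed or random effects) and the heterogeneity statistics
#' that drove the choice.
#'
#' @slot outcome outcome name.
#' @slot beta pooled estimate per one-unit exposure increase.
#' @slot se standard error of `beta`.
#' @slot ciLow,ciHigh 95% Wald interval bounds.
#' @slot pvalue two-sided normal p-value.
#' @slot model `"fixed"` or `"random"`.
#' @slot het [HeterogeneityStats] of the pooled instruments.
#' @slot k number of instruments pooled.
#' @slot scale outcome scale (`"log_odds"` estimates exponentiate to ORs).
#' @slot excludedRsids rsids excluded before pooling (sensitivity runs).
#' @export
setClass("PooledEstimate",
  representation(
    outcome = "character", beta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
    model = "character", het = "HeterogeneityStats",
    k = "integer", scale = "character", excludedRsids = "character"
  ),
  prototype(outcome = NA_character_, excludedRsids = character())
)

setValidity("PooledEstimate", function(object) {
  msg <- character()
  if (!object@model %in% c("fixed", "random"))
    msg <- c(msg, "model must be 'fixed' or 'random'")
  if (!object@scale %in% c("continuous", "log_odds"))
    msg <- c(msg, "scale must be 'continuous' or 'log_odds'")
  if (!is.finite(object@se) || object@se <= 0)
    msg <- c(msg, "se must be > 0")
  if (is.finite(object@beta) &&
      !(object@ciLow < object@beta && object@beta < object@ciHigh))
    msg <- c(msg, "CI must bracket the estimate")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(msg)) msg else TRUE
})

#' InstrumentStrength: first-stage F-statistic and explained variance
#'
#' @slot r2 proportion of exposure variance explained, in \[0, 1).
#' @slot n first-stage (exposure GWAS) sample size.
#' @slot k number of instruments.
#' @slot f the F-statistic `((n - k - 1)/k) * r2/(1 - r2)`.
#' @export
setClass("InstrumentStrength",
  representation(r2 = "numeric", n = "numeric", k = "integer", f = "numeric")
)

setValidity("InstrumentStrength", function(object) {
  msg <- character()
  if (object@r2 < 0 || object@r2 >= 1) msg <- c(msg, "r2 must lie in [0, 1)")
  if (object@f < 0) msg <- c(msg, "f must be >= 0")
  if ((object@f == 0) != (object@r2 == 0))
    msg <- c(msg, "f == 0 iff r2 == 0")
  if (length(msg)) msg else TRUE
})

#' SensitivityReport: baseline estimate plus instrument-exclusion variants
#'
#' @slot baseline the all-instrument [PooledEstimate].
#' @slot variants named list of [PooledEstimate], one per exclusion set.
#' @slot maxAbsShift largest `|beta_variant - beta_baseline|`.
#' @export
setClass("SensitivityReport",
  representation(baseline = "PooledEstimate", variants = "list",
                 maxAbsShift = "numeric")
)

setValidity("SensitivityReport", function(object) {
  msg <- character()
  if (length(object@variants)) {
    if (is.null(names(object@variants)) ||
        anyDuplicated(names(object@variants)))
      msg <- c(msg, "variant labels must be unique and named")
    if (!all(vapply(object@variants, is, logical(1), "PooledEstimate")))
      msg <- c(msg, "variants must be PooledEstimate objects")
    else if (any(vapply(object@variants, function(v) v@k, integer(1)) >=
                 object@baseline@k))
      msg <- c(msg, "every variant must pool fewer instruments than baseline")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameterization of a synthetic two-sample MR study
#'
#' Defines the generative model for synthetic GWAS summary statistics: a
#' small set of independent biallelic instruments with true per-allele
#' exposure effects, a true causal effect of the exposure on the outcome,
#' optional horizontal pleiotropy (a direct variant-outcome effect
#' bypassing the exposure), and the sample sizes that set the sampling
#' variances of the reported betas.
#'
#' @slot seed integer seed fixing all randomness.
#' @slot trueEffect causal effect of a one-unit exposure increase on the
#'   outcome (log-odds for binary outcomes, SD units for continuous).
#' @slot snps `data.frame` with `rsid`, `chromosome`, `effect_allele`,
#'   `other_allele`, `eaf`, `exposure_beta` (true per-allele effect).
#' @slot nExposure first-stage sample size.
#' @slot outcomeKind `"binary"` or `"continuous"`.
#' @slot nCases,nControls case-control counts (binary outcomes).
#' @slot nOutcome sample size (continuous outcomes).
#' @slot pleiotropy named numeric: direct outcome effect per rsid.
#' @slot exposureSd exposure phenotype SD, used for the exposure-beta
#'   standard errors and for the explained-variance denominator.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", trueEffect = "numeric", snps = "data.frame",
    nExposure = "numeric", outcomeKind = "character",
    nCases = "numeric", nControls = "numeric", nOutcome = "numeric",
    pleiotropy = "numeric", exposureSd = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  need <- c("rsid", "chromosome", "effect_allele", "other_allele",
            "eaf", "exposure_beta")
  missing <- setdiff(need, names(object@snps))
  if (length(missing))
    return(sprintf("snps: missing columns %s", paste(missing, collapse = ", ")))
  if (nrow(object@snps) == 0L) msg <- c(msg, "snps: need at least one variant")
  if (any(object@snps$eaf <= 0 | object@snps$eaf >= 1))
    msg <- c(msg, "eaf: must lie strictly in (0, 1)")
  if (anyDuplicated(object@snps$rsid)) msg <- c(msg, "snps: duplicate rsids")
  if (!object@outcomeKind %in% c("binary", "continuous"))
    msg <- c(msg, "outcomeKind: must be 'binary' or 'continuous'")
  if (object@outcomeKind == "binary" &&
      (object@nCases <= 0 || object@nControls <= 0))
    msg <- c(msg, "nCases/nControls: must be positive")
  if (object@outcomeKind == "continuous" && object@nOutcome <= 0)
    msg <- c(msg, "nOutcome: must be positive")
  if (object@nExposure <= 0) msg <- c(msg, "nExposure: must be positive")
  if (object@exposureSd <= 0) msg <- c(msg, "exposureSd: must be positive")
  if (length(object@pleiotropy) &&
      !all(names(object@pleiotropy) %in% object@snps$rsid))
    msg <- c(msg, "pleiotropy: names must be instrument rsids")
  if (length(msg)) msg else TRUE
})
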