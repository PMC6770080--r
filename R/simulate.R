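#' Default instrument panel for the synthetic study
#'
#' Three independent biallelic variants on different chromosomes, modelled
#' on the published serum vitamin E (alpha-tocopherol) instrument: true
#' per-allele exposure effects of 0.03-0.04 mg/L, effect-allele
#' frequencies 0.15-0.21, and one palindromic G/C variant (the rs964184
#' analogue) so that strand inference is exercised by default.
#'
#' @return `data.frame` with columns `rsid`, `chromosome`, `effect_allele`,
#'   `other_allele`, `eaf`, `exposure_beta`.
#' @export
defaultInstrumentSnps <- function() {
  data.frame(
    rsid = c("rs11057830", "rs2108622", "rs964184"),
    chromosome = c("12", "19", "11"),
    effect_allele = c("A", "T", "G"),
    other_allele = c("G", "C", "C"),
    eaf = c(0.15, 0.21, 0.15),
    exposure_beta = c(0.03, 0.03, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Parameterizes the synthetic two-sample study. Defaults emulate the
#' vitamin E / coronary artery disease setting: the three-variant
#' instrument panel of [defaultInstrumentSnps()], an exposure GWAS of
#' n = 7781, and a binary outcome with 60,801 cases and 123,504 controls
#' on the log-odds scale. `exposureSd = 0.45` mg/L is calibrated so the
#' generated exposure standard errors match the published instrument SEs
#' (~0.01) at the default sample size.
#'
#' @param seed integer seed; fixes all randomness of [simulateStudy()].
#' @param trueEffect true causal effect per 1 mg/L exposure increase
#'   (log-odds or SD scale).
#' @param snps instrument panel (see [defaultInstrumentSnps()]).
#' @param nExposure exposure GWAS sample size.
#' @param outcomeKind `"binary"` or `"continuous"`.
#' @param nCases,nControls case/control counts for binary outcomes.
#' @param nOutcome sample size for continuous outcomes.
#' @param pleiotropy named numeric vector of direct variant-outcome
#'   effects (horizontal pleiotropy), e.g. `c(rs964184 = 0.02)`.
#' @param exposureSd exposure phenotype SD in trait units.
#' @return a validated [SimulationConfig].
#' @export
simulationConfig <- function(seed = 1L,
                             trueEffect = 0,
                             snps = defaultInstrumentSnps(),
                             nExposure = 7781,
                             outcomeKind = c("binary", "continuous"),
                             nCases = 60801,
                             nControls = 123504,
                             nOutcome = 188577,
                             pleiotropy = numeric(),
                             exposureSd = 0.45) {
  outcomeKind <- match.arg(outcomeKind)
  tryCatch(
    new("SimulationConfig",
        seed = as.integer(seed), trueEffect = trueEffect, snps = snps,
        nExposure = nExposure, outcomeKind = outcomeKind,
        nCases = nCases, nControls = nControls, nOutcome = nOutcome,
        pleiotropy = pleiotropy, exposureSd = exposureSd),
    error = function(e)
      mrStop(paste("invalid SimulationConfig:", conditionMessage(e)),
             "ivwMR_config_error"))
}

#' Effective sample size of the outcome study
#'
#' For case-control summary statistics on the log-odds scale the sampling
#' variance is governed by `n_cases * n_controls / (n_cases + n_controls)`;
#' for continuous outcomes it is the plain sample size.
#'
#' @param config a [SimulationConfig].
#' @return effective sample size.
#' @export
effectiveSampleSize <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@outcomeKind == "binary")
    config@nCases * config@nControls / (config@nCases + config@nControls)
  else
    config@nOutcome
}

#' Simulate a two-sample GWAS summary-statistic study
#'
#' Generates one exposure table and one outcome table under the structural
#' model of instrumental-variable analysis. For each variant k with true
#' per-allele exposure effect `E_k` and effect-allele frequency `p_k`:
#' \itemize{
#'   \item the reported exposure beta is drawn
#'     `Normal(E_k, sigma_Ek^2)` with
#'     `sigma_Ek = exposureSd / sqrt(2 p_k (1 - p_k) nExposure)`;
#'   \item the true outcome effect is `D*_k = theta * E_k + alpha_k`,
#'     where `theta` is the causal effect and `alpha_k` any horizontal
#'     pleiotropy assigned to the variant;
#'   \item the reported outcome beta is drawn `Normal(D*_k, sigma_Dk^2)`
#'     with `sigma_Dk = 1 / sqrt(2 p_k (1 - p_k) n_eff)` and `n_eff` from
#'     [effectiveSampleSize()] (log-odds scale for binary outcomes,
#'     SD-standardized scale for continuous ones).
#' }
#' Variants are independent (no LD), p-values are two-sided normal
#' p-values computed from beta/se, and reported EAFs equal the configured
#' frequencies on both sides. The generator draws from a single seeded
#' stream in a fixed order — all exposure betas first, then all outcome
#' betas — so a given seed yields byte-identical tables.
#'
#' @param config a [SimulationConfig].
#' @return list with elements `exposure` and `outcome`, both
#'   [GwasAssociations], and `truth` (a `data.frame` of per-variant true
#'   values: `exposure_beta`, `pleiotropy`, `true_outcome_beta`).
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  snps <- config@snps
  K <- nrow(snps)
  p <- snps$eaf
  het2pq <- 2 * p * (1 - p)

  seE <- config@exposureSd / sqrt(het2pq * config@nExposure)
  seD <- 1 / sqrt(het2pq * effectiveSampleSize(config))
  alpha <- rep(0, K)
  if (length(config@pleiotropy))
    alpha[match(names(config@pleiotropy), snps$rsid)] <- config@pleiotropy
  dStar <- config@trueEffect * snps$exposure_beta + alpha

  set.seed(config@seed)
  betaE <- stats::rnorm(K, mean = snps$exposure_beta, sd = seE)
  betaD <- stats::rnorm(K, mean = dStar, sd = seD)

  mkTab <- function(beta, se, n) data.frame(
    rsid = snps$rsid, chromosome = snps$chromosome,
    effect_allele = snps$effect_allele, other_allele = snps$other_allele,
    beta = beta, se = se, eaf = p,
    # two-sided normal p, floored at the smallest positive double so the
    # (0, 1] invariant survives arbitrarily strong associations
    pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n,
    stringsAsFactors = FALSE)

  exposure <- new("GwasAssociations",
    trait = "simulated exposure", scale = "continuous", unitLabel = "mg/L",
    table = mkTab(betaE, seE, config@nExposure),
    provenance = list(source = "simulateStudy", seed = config@seed,
                      n_read = K, n_kept = K, n_skipped = 0L))
  outcome <- new("GwasAssociations",
    trait = "simulated outcome",
    scale = if (config@outcomeKind == "binary") "log_odds" else "continuous",
    unitLabel = if (config@outcomeKind == "binary") "log(OR)" else "SD",
    table = mkTab(betaD, seD,
                  if (config@outcomeKind == "binary")
                    config@nCases + config@nControls else config@nOutcome),
    provenance = list(source = "simulateStudy", seed = config@seed,
                      n_read = K, n_kept = K, n_skipped = 0L))

  list(exposure = exposure, outcome = outcome,
       truth = data.frame(rsid = snps$rsid, true_effect = config@trueEffect,
                          exposure_beta = snps$exposure_beta,
                          pleiotropy = alpha, true_outcome_beta = dStar,
                          stringsAsFactors = FALSE))
}

#' Write a simulated study to disk as reader-compatible fixtures
#'
#' Emits `exposure.tsv` and `outcome.tsv` in the `"default"` column layout
#' (parseable by [readAssociationTable()] with `columnPreset("default")`),
#' plus `truth.tsv` holding the generative parameters (theta and per-SNP
#' pleiotropy) for test harnesses.
#'
#' @param config a [SimulationConfig].
#' @param directory output directory, created if needed.
#' @return invisibly, named character vector of the three file paths.
#' @export
writeFixture <- function(config, directory) {
  study <- simulateStudy(config)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(directory, "exposure.tsv"),
             outcome = file.path(directory, "outcome.tsv"),
             truth = file.path(directory, "truth.tsv"))
  writeTab <- function(tab, path) {
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x)
      format(x, digits = 17, scientific = TRUE, trim = TRUE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeTab(assocTable(study$exposure), paths[["exposure"]])
  writeTab(assocTable(study$outcome), paths[["outcome"]])
  writeTab(study$truth, paths[["truth"]])
  invisible(paths)
}
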