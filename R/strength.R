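#' Variance in the exposure explained by the instruments
#'
#' Under Hardy-Weinberg equilibrium and independent variants, each variant
#' contributes `2 p (1 - p) beta^2` to the variance of the exposure, so
#' \deqn{R^2 = \frac{\sum_k 2\,eaf_k (1 - eaf_k)\, \beta_k^2}{Var(X)}}
#' with `Var(X)` the phenotypic variance of the exposure (in squared trait
#' units, e.g. (mg/L)^2 for a serum vitamin level). The result is clipped
#' into \[0, 1).
#'
#' @param instruments an [InstrumentSet] (or [GwasAssociations]) whose
#'   rows all carry `eaf` and `beta`.
#' @param phenotypeVariance variance of the exposure phenotype, > 0.
#' @return the explained-variance fraction R^2.
#' @export
instrumentR2 <- function(instruments, phenotypeVariance) {
  stopifnot(is(instruments, "GwasAssociations"))
  if (!is.numeric(phenotypeVariance) || length(phenotypeVariance) != 1L ||
      !is.finite(phenotypeVariance) || phenotypeVariance <= 0)
    mrStop("phenotypeVariance must be a single positive value",
           "ivwMR_config_error")
  tab <- instruments@table
  if (nrow(tab) == 0L)
    mrStop("no instruments", "ivwMR_empty_input_error")
  if (any(is.na(tab$eaf)))
    mrStop(paste("instrument(s) missing eaf: cannot compute R^2;",
                 "supply r2 to fStatistic() directly"),
           "ivwMR_missing_eaf_error")
  r2 <- sum(2 * tab$eaf * (1 - tab$eaf) * tab$beta^2) / phenotypeVariance
  min(max(r2, 0), 1 - .Machine$double.eps)
}

#' First-stage F-statistic for instrument strength
#'
#' The standard weak-instrument diagnostic
#' \deqn{F = \frac{n - k - 1}{k} \cdot \frac{R^2}{1 - R^2}}
#' where `n` is the exposure-GWAS sample size, `k` the number of
#' instruments and `R^2` the fraction of exposure variance they explain.
#' Values below ~10 are conventionally taken to signal weak-instrument
#' bias.
#'
#' @param r2 explained-variance fraction in \[0, 1).
#' @param n first-stage sample size (must exceed `k + 1`).
#' @param k number of instruments (>= 1).
#' @return an [InstrumentStrength].
#' @export
fStatistic <- function(r2, n, k) {
  if (!is.numeric(r2) || length(r2) != 1L || r2 < 0 || r2 >= 1)
    mrStop("r2 must lie in [0, 1)", "ivwMR_domain_error")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    mrStop("k must be a positive integer", "ivwMR_domain_error")
  if (!is.numeric(n) || length(n) != 1L || n <= k + 1)
    mrStop("n must exceed k + 1", "ivwMR_domain_error")
  new("InstrumentStrength", r2 = r2, n = n, k = as.integer(k),
      f = ((n - k - 1) / k) * (r2 / (1 - r2)))
}
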