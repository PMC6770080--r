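## 97.5% normal quantile used for all Wald intervals.
.Z975 <- stats::qnorm(0.975)

## Extract the (E_k, D_k, sigma_Dk) triples from kept pairs, with the
## shared precondition checks.
.pairTriples <- function(pairs, minK = 1L, what = "pooling") {
  stopifnot(is(pairs, "HarmonizedPairs"))
  kept <- keptPairs(pairs)
  if (nrow(kept) < minK)
    mrStop(sprintf("%s requires at least %d harmonized instrument(s), have %d",
                   what, minK, nrow(kept)),
           if (nrow(kept) == 0L) "ivwMR_empty_input_error"
           else "ivwMR_insufficient_instruments_error")
  if (any(kept$beta_exposure == 0))
    mrStop("exposure beta of 0: degenerate instrument, Wald ratio undefined",
           "ivwMR_degenerate_instrument_error")
  list(rsid = kept$rsid, E = kept$beta_exposure,
       D = kept$beta_outcome, sD = kept$se_outcome)
}

.newPooled <- function(beta, se, model, het, k, scale, outcome,
                       excluded = character()) {
  new("PooledEstimate",
      outcome = outcome, beta = beta, se = se,
      ciLow = beta - .Z975 * se, ciHigh = beta + .Z975 * se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)),
      model = model, het = het, k = as.integer(k), scale = scale,
      excludedRsids = excluded)
}

.emptyHet <- function() new("HeterogeneityStats", q = 0, df = 0,
                            pHet = NA_real_, i2 = 0, tau2 = 0)

#' Per-variant Wald ratio estimates
#'
#' For each harmonized instrument, the causal effect of a one-unit exposure
#' increase implied by that variant alone: the variant-outcome effect
#' divided by the variant-exposure effect, `D_k / E_k`, with first-order
#' delta-method standard error `sigma_Dk / |E_k|` (the exposure effect is
#' treated as known, consistent with the IVW weights).
#'
#' @param pairs a [HarmonizedPairs].
#' @return `data.frame` with columns `rsid`, `ratio`, `se`.
#' @export
waldRatio <- function(pairs) {
  tr <- .pairTriples(pairs, minK = 1L, what = "Wald estimation")
  data.frame(rsid = tr$rsid, ratio = tr$D / tr$E, se = tr$sD / abs(tr$E),
             stringsAsFactors = FALSE)
}

## Fixed-effect IVW on the raw (E, D, sigma_D) triples:
##   beta = sum(E D / sD^2) / sum(E^2 / sD^2),  se = 1/sqrt(sum(E^2 / sD^2))
.ivwFixedCore <- function(E, D, sD) {
  w <- E^2 / sD^2
  denom <- sum(w)
  list(beta = sum(E * D / sD^2) / denom, se = sqrt(1 / denom), w = w)
}

.hetCore <- function(E, D, sD, betaFixed) {
  w <- E^2 / sD^2
  r <- D / E
  q <- sum(w * (r - betaFixed)^2)
  df <- length(w) - 1
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  c2 <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (c2 > 0) max(0, (q - df) / c2) else 0
  list(q = q, df = df,
       pHet = if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE)
              else NA_real_,
       i2 = i2, tau2 = tau2)
}

#' Fixed-effect inverse-variance weighted estimate
#'
#' Pools the instruments under a common-effect model:
#' \deqn{\hat\beta_{IVW} = \frac{\sum_k E_k D_k \sigma_{Dk}^{-2}}
#'   {\sum_k E_k^2 \sigma_{Dk}^{-2}}, \qquad
#'   SE(\hat\beta_{IVW}) = \sqrt{\frac{1}{\sum_k E_k^2 \sigma_{Dk}^{-2}}}}
#' where \eqn{E_k} is the per-allele exposure effect and \eqn{D_k} the
#' per-allele outcome effect with standard error \eqn{\sigma_{Dk}}. This is
#' algebraically identical to a fixed-effect meta-analysis of the per-SNP
#' Wald ratios weighted by their inverse squared delta-method SEs.
#' Heterogeneity statistics are attached (absent for a single instrument).
#'
#' @param pairs a [HarmonizedPairs] with at least one kept instrument.
#' @param outcome outcome label for the result (defaults to the pairs'
#'   outcome trait).
#' @return a [PooledEstimate] with `model == "fixed"`.
#' @export
ivwFixed <- function(pairs, outcome = pairs@outcomeTrait) {
  tr <- .pairTriples(pairs, minK = 1L, what = "fixed-effect IVW")
  fit <- .ivwFixedCore(tr$E, tr$D, tr$sD)
  het <- if (length(tr$E) >= 2L) {
    h <- .hetCore(tr$E, tr$D, tr$sD, fit$beta)
    new("HeterogeneityStats", q = h$q, df = h$df, pHet = h$pHet,
        i2 = h$i2, tau2 = h$tau2)
  } else .emptyHet()
  .newPooled(fit$beta, fit$se, "fixed", het, length(tr$E), pairs@scale,
             outcome)
}

#' Heterogeneity of per-variant Wald ratios
#'
#' Cochran's Q of the Wald ratios about the fixed-effect pooled estimate,
#' using the fixed IVW weights on the ratio scale
#' (\eqn{w_k = E_k^2 \sigma_{Dk}^{-2}}): \eqn{Q = \sum_k w_k (r_k -
#' \hat\beta)^2} on `k - 1` degrees of freedom, with upper-tail chi-square
#' p-value, \eqn{I^2 = \max(0, (Q - df)/Q)} and the DerSimonian-Laird
#' moment estimate \eqn{\hat\tau^2 = \max\{0, (Q - df) / (\sum w_k -
#' \sum w_k^2 / \sum w_k)\}}. Excess heterogeneity among instruments is the
#' standard signal of horizontal pleiotropy in this design.
#'
#' @param pairs a [HarmonizedPairs] with at least two kept instruments.
#' @param betaFixed optionally, the fixed-effect pooled estimate to measure
#'   dispersion around; computed from `pairs` when omitted.
#' @return a [HeterogeneityStats].
#' @export
heterogeneity <- function(pairs, betaFixed = NULL) {
  tr <- .pairTriples(pairs, minK = 2L, what = "heterogeneity")
  if (is.null(betaFixed))
    betaFixed <- .ivwFixedCore(tr$E, tr$D, tr$sD)$beta
  if (is(betaFixed, "PooledEstimate")) betaFixed <- betaFixed@beta
  h <- .hetCore(tr$E, tr$D, tr$sD, betaFixed)
  new("HeterogeneityStats", q = h$q, df = h$df, pHet = h$pHet,
      i2 = h$i2, tau2 = h$tau2)
}

#' Random-effects (DerSimonian-Laird) IVW estimate
#'
#' Re-pools the Wald ratios with additive between-variant variance:
#' weights \eqn{w^*_k = 1/(se_k^2 + \hat\tau^2)} where \eqn{se_k} is the
#' delta-method Wald-ratio SE and \eqn{\hat\tau^2} the DerSimonian-Laird
#' estimate. When \eqn{\hat\tau^2 = 0} the result coincides with
#' [ivwFixed()]; otherwise the standard error is strictly larger,
#' acknowledging effect heterogeneity (e.g. from pleiotropy).
#'
#' @inheritParams ivwFixed
#' @return a [PooledEstimate] with `model == "random"`.
#' @export
ivwRandom <- function(pairs, outcome = pairs@outcomeTrait) {
  tr <- .pairTriples(pairs, minK = 2L, what = "random-effects IVW")
  fit <- .ivwFixedCore(tr$E, tr$D, tr$sD)
  h <- .hetCore(tr$E, tr$D, tr$sD, fit$beta)
  r <- tr$D / tr$E
  seW <- tr$sD / abs(tr$E)
  wStar <- 1 / (seW^2 + h$tau2)
  beta <- sum(wStar * r) / sum(wStar)
  se <- sqrt(1 / sum(wStar))
  het <- new("HeterogeneityStats", q = h$q, df = h$df, pHet = h$pHet,
             i2 = h$i2, tau2 = h$tau2)
  .newPooled(beta, se, "random", het, length(r), pairs@scale, outcome)
}

#' Pool instruments with heterogeneity-driven model selection
#'
#' The headline estimator: computes the heterogeneity test and selects the
#' random-effects model iff there are at least two instruments and the
#' heterogeneity p-value falls below `hetAlpha`; otherwise the fixed-effect
#' model is used. The chosen model and the heterogeneity statistics are
#' recorded in the result, so report tables can show, per outcome, the
#' model, I-squared and heterogeneity p alongside the estimate.
#'
#' @inheritParams ivwFixed
#' @param hetAlpha significance level of the heterogeneity test driving
#'   model choice (default 0.05).
#' @return a [PooledEstimate] with `model` set to the selected model.
#' @export
poolWithModelSelection <- function(pairs, hetAlpha = 0.05,
                                   outcome = pairs@outcomeTrait) {
  if (!is.numeric(hetAlpha) || length(hetAlpha) != 1L ||
      hetAlpha <= 0 || hetAlpha >= 1)
    mrStop("hetAlpha must be a single value in (0, 1)", "ivwMR_config_error")
  fixed <- ivwFixed(pairs, outcome = outcome)
  if (fixed@k >= 2L && !is.na(fixed@het@pHet) && fixed@het@pHet < hetAlpha)
    ivwRandom(pairs, outcome = outcome)
  else
    fixed
}

#' Express a log-odds pooled estimate as an odds ratio
#'
#' Exponentiates the estimate and its 95% CI bounds, giving the OR per
#' one-unit increase in the genetically predicted exposure. Ordering of
#' the bounds is preserved.
#'
#' @param pooled a [PooledEstimate] on the `"log_odds"` scale.
#' @return list with `or`, `ciLow`, `ciHigh`.
#' @export
toOddsRatio <- function(pooled) {
  stopifnot(is(pooled, "PooledEstimate"))
  if (pooled@scale != "log_odds")
    mrStop("toOddsRatio requires a log-odds scale estimate",
           "ivwMR_scale_mismatch_error")
  list(or = exp(pooled@beta), ciLow = exp(pooled@ciLow),
       ciHigh = exp(pooled@ciHigh))
}
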