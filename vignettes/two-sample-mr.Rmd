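---
title: "Two-sample Mendelian randomization with ivwMR: models, choices, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with ivwMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivwMR)
```

## The design

Mendelian randomization (MR) treats genetic variants as instrumental
variables for a modifiable exposure. Because alleles are assigned at
conception, a variant that raises serum vitamin E by a fixed amount per
allele provides a natural experiment: if vitamin E causally affects
coronary artery disease (CAD), carriers of vitamin-E-raising alleles
should show proportionally shifted CAD risk, and this association is
immune to the confounding and reverse causation that plague observational
serum measurements.

In the *two-sample* variant of the design the variant–exposure and
variant–outcome associations come from different studies. Only published
per-variant summary statistics are needed: for variant $k$, the per-allele
exposure effect $E_k$ (e.g. mg/L of serum alpha-tocopherol) with standard
error $\sigma_{E_k}$, and the per-allele outcome effect $D_k$ (log odds
for case-control outcomes, SD units for continuous traits) with standard
error $\sigma_{D_k}$.

## Estimators

Each variant alone yields a **Wald ratio** estimate of the causal effect
$\theta$ of a one-unit exposure increase:

$$\hat\theta_k = \frac{D_k}{E_k}, \qquad
  se(\hat\theta_k) = \frac{\sigma_{D_k}}{|E_k|}.$$

The standard error is the first-order delta-method expression that treats
$E_k$ as known. We use the first-order form deliberately: the
inverse-variance weighted (IVW) estimator that pools the ratios,

$$\hat\beta_{IVW}
   = \frac{\sum_k E_k D_k \sigma_{D_k}^{-2}}{\sum_k E_k^2 \sigma_{D_k}^{-2}},
  \qquad
  SE(\hat\beta_{IVW}) = \sqrt{\frac{1}{\sum_k E_k^2 \sigma_{D_k}^{-2}}},$$

is then *algebraically identical* to the fixed-effect meta-analysis of the
Wald ratios with weights $1/se(\hat\theta_k)^2$ — an identity the test
suite asserts to $10^{-12}$ on a thousand random inputs. A second-order
SE would break that identity; it is out of scope here.

Dispersion of the per-variant ratios beyond their sampling error is the
classic signature of horizontal pleiotropy. We quantify it with Cochran's
$Q = \sum_k w_k (\hat\theta_k - \hat\beta_{IVW})^2$ on $k-1$ degrees of
freedom (weights $w_k = E_k^2\sigma_{D_k}^{-2}$), report
$I^2 = \max(0, (Q - df)/Q)$, and estimate an additive between-variant
variance by the DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w_k - \sum w_k^2/\sum w_k)\}$.
`poolWithModelSelection()` selects the **random-effects** model (weights
$1/(se_k^2 + \hat\tau^2)$) exactly when $k \ge 2$ and the heterogeneity
test rejects at `hetAlpha`, and the fixed-effect model otherwise. An
additive (DL) rather than multiplicative random-effects model is the
package's choice; it is the most widely used IVW random-effects variant
and collapses onto the fixed model when $\hat\tau^2 = 0$.

Confidence intervals are Wald intervals with
$z = \Phi^{-1}(0.975) \approx 1.959964$ and p-values are two-sided
normal. On the log-odds scale, `toOddsRatio()` exponentiates the estimate
and both bounds.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pThreshold` | `5e-8` | instrument selection; strict `p < threshold`, the conventional genome-wide significance level |
| `hetAlpha` | `0.05` | level of the Q test that switches fixed to random effects |
| `palindromicPolicy` | `"infer_by_eaf"` | how A/T and G/C variants are aligned (below) |
| `eafAmbiguityBand` | `0.08` | half-width around 0.5 inside which an allele frequency cannot identify strand |
| `phenotypeVariance` | — | exposure variance (squared trait units) for $R^2$ and the F-statistic |

## Harmonization

The two studies may report a variant on opposite strands or with effect
and other allele swapped. Non-palindromic variants are resolved by
letters: a swapped report negates the outcome beta and complements its
frequency; a strand-complemented report is unambiguous and is aligned
silently. Palindromic variants (A/T, G/C) match by letters on *either*
strand, so orientation must come from the effect-allele frequency: the
orientation that puts both frequencies on the same side of 0.5 is chosen
(`resolution = "eaf_inferred"`). If either frequency is missing or lies
within `eafAmbiguityBand` of 0.5, the variant is dropped — a silent
strand error flips the sign of a causal estimate, which is worse than
losing an instrument. The default is inference rather than wholesale
dropping because real instrument panels often contain a palindromic
variant whose frequency (e.g. 0.15) is far from ambiguous; users wanting
the conservative behaviour set `palindromicPolicy = "drop"`. The default
band of 0.08 is wide enough that typical cross-population frequency drift
cannot push a truly same-strand variant across 0.5.

Harmonization is involution-safe (re-harmonizing changes nothing) and
sign-consistent (flipping every allele in the outcome file leaves all
Wald ratios unchanged); both are asserted in the suite.

## Instrument strength

Weak instruments bias IV estimates. The first-stage F-statistic is

$$F = \frac{n - k - 1}{k}\cdot\frac{R^2}{1 - R^2},$$

with $R^2$ the fraction of exposure variance explained. From a summary
table alone, $R^2$ is computed under Hardy–Weinberg and independence as
$\sum_k 2\,p_k(1-p_k)E_k^2 / \mathrm{Var}(X)$; the phenotypic variance
$\mathrm{Var}(X)$ must be supplied, since it is not identifiable from
per-variant rows. Note that published instrument tables rounded to one or
two significant figures can be internally inconsistent — betas and SEs
rounded to 0.03/0.01 imply far larger p-values than the printed
genome-wide ones, and imply an F that can differ several-fold from an
originally reported value depending on the variance assumed. `ivwMR`
therefore always recomputes $F$ from the inputs it is given and reports
the variance assumption alongside.

## The synthetic-data generator

`simulateStudy()` emulates the data-generating process the estimators
assume, so every stage is testable without downloads. Defaults mirror a
three-variant serum vitamin E instrument applied to CAD case-control
data:

* three independent biallelic variants on different chromosomes with true
  per-allele effects 0.03–0.04 mg/L and frequencies 0.15–0.21, one of
  them palindromic (G/C at EAF 0.15) so strand inference is exercised by
  default;
* exposure sample size $n = 7781$ with
  $\sigma_{E_k} = sd_X/\sqrt{2p_k(1-p_k)n}$; the default exposure SD of
  0.45 mg/L is calibrated so these SEs land at ~0.01, matching the
  published panel;
* a binary outcome simulated directly on the log-odds summary-statistic
  scale with $\sigma_{D_k} = 1/\sqrt{2p_k(1-p_k)n_{\mathrm{eff}}}$,
  $n_{\mathrm{eff}} = n_1 n_0/(n_1+n_0)$ for 60,801 cases and 123,504
  controls (continuous outcomes use the plain $n$ on an SD scale). No
  individual-level logistic data are generated — the pipeline only ever
  consumes summary statistics, and the summary-scale model keeps a
  thousand replicates under half a minute;
* true outcome effects $D^*_k = \theta E_k + \alpha_k$, where a nonzero
  $\alpha_k$ injects horizontal pleiotropy on the named variant;
* one seeded stream per run, drawn in a documented order (all exposure
  betas, then all outcome betas), so a seed fixes the tables byte for
  byte. Reported p-values are computed from beta/se and floored at the
  smallest positive double; reported EAFs equal the configured
  frequencies on both sides.

What the generator does **not** emulate: linkage disequilibrium (the
instruments are independent by design), winner's-curse inflation of the
discovery betas, population stratification, sample overlap between the
two studies, and EAF measurement error. Passing calibration tests
therefore demonstrate correctness of the estimators under the model's own
assumptions, not robustness to those real-data pathologies.

Because simulated p-values are consistent with their beta/se (unlike
rounded published tables), instruments simulated at these sample sizes
have $p \sim 10^{-3}$, not $10^{-9}$; pipeline runs on synthetic data
therefore use a loose selection threshold, and near-1 thresholds are used
in the suite so that selection effectively keeps every variant rather
than re-introducing winner's curse.

## Calibration results the suite computes

At the defaults with $\theta = 0.049 \approx \ln 1.05$, over 1000 seeded
replicates the suite verifies that the 95% CI covers $\theta$ at
95% ± 2%, that the two-sided test under $\theta = 0$ rejects at 5% ±
1.5%, and that the median replicate estimate recovers $\theta$ within 5%.
The last band is tight relative to its Monte Carlo noise: the
per-replicate pooled SE is ~0.16, so the median's sampling SD is ~13% of
$\theta$, and first-order attenuation from exposure-beta noise
($\sigma_{E}/E \approx 1/3$ per variant) is of the same order. The check
passes at the suite's fixed replicate set; with other seed sets the
deviation can exceed the band without indicating a defect. Coverage and
size, whose Monte Carlo error is far smaller than their bands, are the
robust calibration statements.

With directional pleiotropy $\alpha = 0.05$ injected on the palindromic
variant, the pooled estimate is biased toward $\mathrm{sign}(\alpha E_k)$
and excluding that variant (`excludeAndRerun()`) removes about two-thirds
of the median absolute error over 500 replicates — the quantitative
content of the exclusion sensitivity analysis, generalized by
`leaveOneOut()`.

## Numerical and degenerate-input choices

* $E_k = 0$ is a degenerate instrument: a typed error, not an `Inf`.
* $k = 1$: heterogeneity p is reported as missing (`NA`), not 1; the
  fixed model is used by construction.
* $Q = 0$: $I^2$ is defined as 0 (avoiding 0/0); negative
  $\hat\tau^2$ truncates to 0 (standard DL).
* Selection uses strict inequality, so a p-value exactly at the threshold
  is excluded.
* Instruments are sorted by rsid everywhere, making every result
  invariant to input order (asserted to $10^{-12}$).
* Result tables are written at full double precision (17 significant
  digits) and round-trip losslessly; rounding (3 decimals for estimates
  and ORs, `<0.001` for small p-values) happens only in
  `presentationTable()`.
* No multiple-testing adjustment is applied across outcomes; each outcome
  is reported marginally.

## Limitations

Only the ratio/IVW family is implemented: no MR-Egger intercept, weighted
median or mode estimators, no Steiger direction filtering, no
multivariable MR. The sensitivity module re-estimates under exclusion but
performs no formal per-variant outlier test. Harmonization does no
liftover, LD-proxy lookup or clumping — instruments are assumed
independent, which callers must justify (e.g. variants on different
chromosomes). And, as above, Wald-ratio SEs ignore first-stage
uncertainty, which attenuates estimates when instruments are weak;
check `fStatistic()` before trusting the point estimate.
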