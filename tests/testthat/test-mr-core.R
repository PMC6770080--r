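test_that("Wald ratios follow the delta-method arithmetic", {
  p <- makePairs(E = c(0.04, 0.05, 0.03), D = c(0.02, 0, 0.0015),
                 sD = c(0.005, 0.003, 0.0004))
  w <- waldRatio(p)
  expect_equal(w$ratio, c(0.5, 0, 0.05))
  expect_equal(w$se, c(0.125, 0.06, 0.0004 / 0.03))
  # sign(ratio) = sign(D) * sign(E), also for negative exposure betas
  pn <- makePairs(E = c(-0.04, -0.04), D = c(0.02, -0.02), sD = 0.005)
  wn <- waldRatio(pn)
  expect_equal(wn$ratio, c(-0.5, 0.5))
  expect_equal(wn$se, c(0.125, 0.125))
  expect_error(waldRatio(makePairs(E = 0, D = 0.1, sD = 0.01)),
               class = "ivwMR_degenerate_instrument_error")
})

test_that("fixed IVW reduces correctly for one instrument and symmetric pairs", {
  p1 <- makePairs(E = 0.04, D = 0.02, sD = 0.005)
  f1 <- ivwFixed(p1)
  expect_equal(estimate(f1), 0.5)
  expect_equal(stdError(f1), 0.125)
  expect_equal(modelUsed(f1), "fixed")
  expect_true(is.na(hetStats(f1)@pHet))

  # identical ratios 0.5 with identical Wald SEs 0.1 (E = 1 => sD = 0.1)
  p2 <- makePairs(E = c(1, 1), D = c(0.5, 0.5), sD = c(0.1, 0.1))
  f2 <- ivwFixed(p2)
  expect_equal(estimate(f2), 0.5)
  expect_equal(stdError(f2), 0.1 / sqrt(2))
  expect_equal(hetStats(f2)@q, 0)
})

test_that("direct Eq-form IVW equals a weighted mean of Wald ratios", {
  p <- makePairs(E = c(0.03, 0.03, 0.04), D = c(0.0015, 0.0012, 0.0020),
                 sD = c(0.0005, 0.0004, 0.0006))
  f <- ivwFixed(p)
  w <- waldRatio(p)
  wt <- 1 / w$se^2
  expect_equal(estimate(f), sum(wt * w$ratio) / sum(wt), tolerance = 1e-12)
  expect_equal(stdError(f), sqrt(1 / sum(wt)), tolerance = 1e-12)
})

test_that("fixed and random IVW match metafor on random inputs", {
  set.seed(20260924)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    p <- makePairs(E = rnorm(k, 0.03, 0.008) + 0.01,
                   D = rnorm(k, 0.002, 0.003),
                   sD = runif(k, 1e-4, 1e-2))
    w <- waldRatio(p)
    fe <- suppressWarnings(metafor::rma(yi = w$ratio, sei = w$se,
                                        method = "FE"))
    dl <- suppressWarnings(metafor::rma(yi = w$ratio, sei = w$se,
                                        method = "DL"))
    f <- ivwFixed(p); r <- ivwRandom(p)
    expect_equal(estimate(f), as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(stdError(f), as.numeric(fe$se), tolerance = 1e-10)
    expect_equal(hetStats(f)@q, as.numeric(fe$QE), tolerance = 1e-10)
    expect_equal(hetStats(f)@pHet, as.numeric(fe$QEp), tolerance = 1e-10)
    expect_equal(hetStats(r)@tau2, as.numeric(dl$tau2), tolerance = 1e-10)
    expect_equal(estimate(r), as.numeric(dl$beta), tolerance = 1e-10)
    expect_equal(stdError(r), as.numeric(dl$se), tolerance = 1e-10)
    # CI and two-sided p agree with the normal reference
    expect_equal(pValue(f), 2 * pnorm(-abs(estimate(f) / stdError(f))),
                 tolerance = 1e-12)
    expect_equal(unname(diff(confInt(f))), 2 * qnorm(0.975) * stdError(f),
                 tolerance = 1e-12)
  }
})

test_that("heterogeneity statistics match hand computations", {
  # three identical ratios: no dispersion at all
  p0 <- makePairs(E = c(1, 1, 1), D = c(0.3, 0.3, 0.3), sD = c(0.1, 0.2, 0.3))
  h0 <- heterogeneity(p0)
  expect_equal(h0@q, 0, tolerance = 1e-12)
  expect_equal(h0@i2, 0)
  expect_equal(h0@tau2, 0)
  expect_equal(h0@pHet, 1, tolerance = 1e-12)

  # ratios (0, 1) with unit weights: Q = w*(r - mean)^2 summed = 0.5
  p1 <- makePairs(E = c(1, 1), D = c(0, 1), sD = c(1, 1))
  h1 <- heterogeneity(p1)
  expect_equal(h1@q, 0.5)
  expect_equal(h1@df, 1)
  expect_equal(h1@pHet, pchisq(0.5, 1, lower.tail = FALSE))
  expect_equal(h1@i2, 0)   # Q < df truncates to zero

  expect_error(heterogeneity(makePairs(E = 1, D = 1, sD = 1)),
               class = "ivwMR_insufficient_instruments_error")
})

test_that("DerSimonian-Laird random effects match the closed form", {
  # two ratios (0, 1) with Wald SE 0.1 each: w = 100, Q = 50
  p <- makePairs(E = c(1, 1), D = c(0, 1), sD = c(0.1, 0.1))
  h <- heterogeneity(p)
  expect_equal(h@q, 50)
  tau2 <- (50 - 1) / (200 - 20000 / 200)
  expect_equal(h@tau2, tau2)
  r <- ivwRandom(p)
  expect_equal(estimate(r), 0.5)           # symmetry
  expect_equal(stdError(r), sqrt(1 / (2 / (0.01 + tau2))))
  expect_gt(stdError(r), stdError(ivwFixed(p)))

  # zero between-variant variance: random collapses onto fixed
  pz <- makePairs(E = c(1, 1, 1), D = c(0.30, 0.31, 0.29), sD = c(1, 1, 1))
  expect_equal(hetStats(ivwRandom(pz))@tau2, 0)
  expect_equal(estimate(ivwRandom(pz)), estimate(ivwFixed(pz)),
               tolerance = 1e-12)
  expect_equal(stdError(ivwRandom(pz)), stdError(ivwFixed(pz)),
               tolerance = 1e-12)
})

test_that("model selection follows the heterogeneity test", {
  # two equal-weight ratios placed so the Q test lands exactly at p = 0.15
  d <- sqrt(2 * qchisq(0.85, df = 1))
  pFixed <- makePairs(E = c(1, 1), D = c(0, d), sD = c(1, 1))
  selF <- poolWithModelSelection(pFixed, hetAlpha = 0.05)
  expect_equal(hetStats(selF)@pHet, 0.15, tolerance = 1e-12)
  expect_equal(modelUsed(selF), "fixed")

  # strongly dispersed ratios: p_het < 0.001 selects random effects
  pRand <- makePairs(E = c(1, 1), D = c(0, 10), sD = c(1, 1))
  selR <- poolWithModelSelection(pRand, hetAlpha = 0.05)
  expect_lt(hetStats(selR)@pHet, 0.001)
  expect_equal(modelUsed(selR), "random")

  # one instrument: fixed, heterogeneity absent
  sel1 <- poolWithModelSelection(makePairs(E = 0.04, D = 0.002, sD = 0.001))
  expect_equal(modelUsed(sel1), "fixed")
  expect_true(is.na(hetStats(sel1)@pHet))
})

test_that("odds-ratio transform exponentiates estimate and CI bounds", {
  p <- makePairs(E = c(1, 1), D = c(0, 0), sD = c(0.5, 0.5),
                 scale = "log_odds")
  or0 <- toOddsRatio(ivwFixed(p))
  se <- stdError(ivwFixed(p))
  expect_equal(or0$or, 1)
  expect_equal(or0$ciLow, exp(-qnorm(0.975) * se))
  expect_equal(or0$ciHigh, exp(qnorm(0.975) * se))

  pe <- new("PooledEstimate", outcome = "x", beta = 0.0488, se = 0.006,
            ciLow = 0.0488 - qnorm(0.975) * 0.006,
            ciHigh = 0.0488 + qnorm(0.975) * 0.006,
            pvalue = 2 * pnorm(-0.0488 / 0.006), model = "fixed",
            het = new("HeterogeneityStats"), k = 3L, scale = "log_odds")
  or <- toOddsRatio(pe)
  expect_equal(or$or, exp(0.0488), tolerance = 1e-12)
  expect_equal(round(or$or, 3), 1.050)
  expect_equal(round(or$ciLow, 3), 1.038)
  expect_equal(round(or$ciHigh, 3), 1.062)
  expect_true(or$ciLow < or$or && or$or < or$ciHigh)

  cont <- ivwFixed(makePairs(E = 1, D = 1, sD = 1))
  expect_error(toOddsRatio(cont), class = "ivwMR_scale_mismatch_error")
})

test_that("explained variance and F-statistic follow their closed forms", {
  one <- makeAssociations(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.2, se = 0.01, eaf = 0.5, pvalue = 1e-9))
  expect_equal(instrumentR2(one, 1), 0.2^2 / 2)

  panel <- makeAssociations(vitaminEInstrumentTable())
  v <- 0.2025
  expected <- (2 * 0.15 * 0.85 * 0.0009 + 2 * 0.21 * 0.79 * 0.0009 +
               2 * 0.15 * 0.85 * 0.0016) / v
  expect_equal(instrumentR2(panel, v), expected, tolerance = 1e-12)

  zero <- makeAssociations(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0, se = 0.01, eaf = 0.3, pvalue = 1e-9))
  expect_equal(instrumentR2(zero, 1), 0)

  noEaf <- makeAssociations(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.01, pvalue = 1e-9))
  expect_error(instrumentR2(noEaf, 1), class = "ivwMR_missing_eaf_error")

  expect_equal(fStatistic(0, 100, 3)@f, 0)
  expect_equal(fStatistic(0.5, 103, 1)@f, 101)
  # inverting the published F = 48 at n = 7781, k = 3 gives r2 ~ 0.018186
  expect_equal(fStatistic(0.018186, 7781, 3)@f, 48.0, tolerance = 1e-3)
  expect_error(fStatistic(1, 100, 3), class = "ivwMR_domain_error")
  expect_error(fStatistic(0.5, 4, 3), class = "ivwMR_domain_error")
})

test_that("pooling is order-invariant and unit-change equivariant", {
  set.seed(99)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    E <- rnorm(k, 0.03, 0.008) + 0.01
    D <- rnorm(k, 0.002, 0.002)
    sD <- runif(k, 1e-4, 5e-3)
    p <- makePairs(E, D, sD)
    perm <- sample(k)
    pp <- makePairs(E[perm], D[perm], sD[perm],
                    rsid = sprintf("rs%03d", perm))
    for (fn in list(ivwFixed, ivwRandom, poolWithModelSelection)) {
      a <- fn(p); b <- fn(pp)
      expect_equal(estimate(a), estimate(b), tolerance = 1e-12)
      expect_equal(stdError(a), stdError(b), tolerance = 1e-12)
      expect_equal(hetStats(a)@q, hetStats(b)@q, tolerance = 1e-12)
    }
    # rescaling exposure units by c divides estimate and SE by c
    cc <- 2.7
    ps <- makePairs(cc * E, D, sD)
    expect_equal(estimate(ivwFixed(ps)), estimate(ivwFixed(p)) / cc,
                 tolerance = 1e-12)
    expect_equal(stdError(ivwFixed(ps)), stdError(ivwFixed(p)) / cc,
                 tolerance = 1e-12)
    # random-effects SE never undercuts the fixed-effect SE
    expect_gte(stdError(ivwRandom(p)), stdError(ivwFixed(p)) - 1e-15)
  }
})
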