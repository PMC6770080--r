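exposure3 <- function() {
  selectInstruments(makeAssociations(vitaminEInstrumentTable()), 5e-8)
}

test_that("matching, swapped and strand-complement alleles are aligned", {
  ex <- makeAssociations(data.frame(
    rsid = c("rs1", "rs2", "rs3"), effect_allele = c("A", "A", "A"),
    other_allele = c("G", "G", "G"), beta = 0.03, se = 0.01,
    eaf = 0.85, pvalue = 1e-9))
  out <- makeAssociations(data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "G", "T"),   # direct / swapped / other strand
    other_allele = c("G", "A", "C"),
    beta = 0.02, se = 0.005, eaf = c(0.85, 0.15, 0.85)))
  h <- keptPairs(harmonize(ex, out))
  h <- h[order(h$rsid), ]
  expect_equal(h$resolution, c("direct", "flipped", "direct"))
  expect_equal(h$beta_outcome, c(0.02, -0.02, 0.02))
  expect_equal(h$eaf_outcome, c(0.85, 0.85, 0.85))
  expect_equal(h$flip_applied, c(FALSE, TRUE, FALSE))
})

test_that("palindromic variants are resolved by allele frequency or dropped", {
  # rs964184 analogue: exposure (G,C) eaf 0.15; outcome reports (C,G) with
  # eaf 0.86 -> the outcome's C matches the complement of the exposure's
  # other allele: swapped orientation, frequencies agree after the swap
  ex <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "G", other_allele = "C",
    beta = 0.04, se = 0.01, eaf = 0.15, pvalue = 1e-11))
  out <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "C", other_allele = "G",
    beta = 0.03, se = 0.005, eaf = 0.86))
  h <- keptPairs(harmonize(ex, out, palindromicPolicy = "infer_by_eaf"))
  expect_equal(h$resolution, "eaf_inferred")
  expect_equal(h$beta_outcome, -0.03)
  expect_true(h$palindromic)

  # same-letter, same-side frequencies: kept without a sign change
  out2 <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "G", other_allele = "C",
    beta = 0.03, se = 0.005, eaf = 0.14))
  h2 <- keptPairs(harmonize(ex, out2))
  expect_equal(h2$beta_outcome, 0.03)
  expect_false(h2$flip_applied)

  # opposite-side frequencies with same letters: other strand, sign flips
  out3 <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "G", other_allele = "C",
    beta = 0.03, se = 0.005, eaf = 0.86))
  h3 <- keptPairs(harmonize(ex, out3))
  expect_equal(h3$beta_outcome, -0.03)
  expect_true(h3$flip_applied)

  # ambiguous or missing frequency, or a drop-all policy: dropped
  outAmb <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "G", other_allele = "C",
    beta = 0.03, se = 0.005, eaf = 0.55))
  expect_equal(nInstruments(harmonize(ex, outAmb)), 0L)
  outNA <- makeAssociations(data.frame(
    rsid = "rs964184", effect_allele = "G", other_allele = "C",
    beta = 0.03, se = 0.005))
  expect_equal(nInstruments(harmonize(ex, outNA)), 0L)
  expect_equal(nInstruments(harmonize(ex, out2, palindromicPolicy = "drop")),
               0L)
})

test_that("instruments absent from the outcome are dropped with a warning", {
  ex <- exposure3()
  out <- makeAssociations(vitaminEInstrumentTable()[1:2, ],
                          scale = "log_odds")
  expect_warning(h <- harmonize(ex, out),
                 class = "ivwMR_absent_instruments_warning")
  expect_equal(nInstruments(h), 2L)
  expect_equal(droppedPairs(h)$rsid, "rs964184")
  expect_equal(unname(h@log["dropped_absent"]), 1L)
})

test_that("harmonization is involution-safe", {
  cfg <- simulationConfig(seed = 11, trueEffect = 0.05)
  st <- simulateStudy(cfg)
  ex <- selectInstruments(st$exposure, 0.999999)
  h1 <- harmonize(ex, st$outcome)
  h2 <- harmonize(ex, harmonizedOutcome(h1))
  k1 <- keptPairs(h1); k2 <- keptPairs(h2)
  expect_equal(k2$beta_outcome, k1$beta_outcome, tolerance = 1e-15)
  expect_equal(k2$eaf_outcome, k1$eaf_outcome, tolerance = 1e-15)
  expect_false(any(k2$flip_applied))
})

test_that("flipping outcome file alleles leaves Wald ratios unchanged", {
  for (seed in 1:5) {
    cfg <- simulationConfig(seed = seed, trueEffect = 0.05)
    st <- simulateStudy(cfg)
    ex <- selectInstruments(st$exposure, 0.999999)
    tab <- assocTable(st$outcome)
    flipped <- tab
    flipped$effect_allele <- tab$other_allele
    flipped$other_allele <- tab$effect_allele
    flipped$beta <- -tab$beta
    flipped$eaf <- 1 - tab$eaf
    outFlip <- makeAssociations(flipped, scale = "log_odds")
    w1 <- waldRatio(harmonize(ex, st$outcome))
    w2 <- waldRatio(harmonize(ex, outFlip))
    expect_equal(w2$ratio, w1$ratio, tolerance = 1e-12)
    expect_equal(w2$se, w1$se, tolerance = 1e-12)
  }
})
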