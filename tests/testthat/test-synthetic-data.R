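test_that("the generator is deterministic in its seed", {
  cfg1 <- simulationConfig(seed = 1, trueEffect = 0.05)
  a <- simulateStudy(cfg1)
  b <- simulateStudy(simulationConfig(seed = 1, trueEffect = 0.05))
  expect_identical(assocTable(a$exposure), assocTable(b$exposure))
  expect_identical(assocTable(a$outcome), assocTable(b$outcome))
  c2 <- simulateStudy(simulationConfig(seed = 2, trueEffect = 0.05))
  expect_false(identical(assocTable(a$exposure), assocTable(c2$exposure)))
})

test_that("generated tables carry the configured structure", {
  cfg <- simulationConfig(seed = 4, trueEffect = log(1.05))
  st <- simulateStudy(cfg)
  ex <- assocTable(st$exposure); out <- assocTable(st$outcome)
  expect_equal(ex$rsid, defaultInstrumentSnps()$rsid)
  expect_equal(out$eaf, ex$eaf)
  expect_equal(outcomeScale(harmonize(selectInstruments(st$exposure, 0.999999),
                                      st$outcome)), "log_odds")
  # exposure SEs are calibrated to ~0.01 at the published sample size
  expect_true(all(abs(ex$se - 0.01) < 0.002))
  # outcome SE follows 1/sqrt(2p(1-p) n_eff)
  neff <- effectiveSampleSize(cfg)
  expect_equal(out$se, 1 / sqrt(2 * out$eaf * (1 - out$eaf) * neff),
               tolerance = 1e-12)
  # p-values are consistent with beta/se
  expect_equal(out$pvalue, 2 * pnorm(-abs(out$beta / out$se)),
               tolerance = 1e-12)
  expect_equal(st$truth$true_outcome_beta,
               log(1.05) * st$truth$exposure_beta)
})

test_that("config validation names the offending field", {
  expect_error(simulationConfig(seed = 1, nExposure = -5), "nExposure",
               class = "ivwMR_config_error")
  bad <- defaultInstrumentSnps(); bad$eaf[1] <- 1.2
  expect_error(simulationConfig(seed = 1, snps = bad), "eaf",
               class = "ivwMR_config_error")
  expect_error(simulationConfig(seed = 1, pleiotropy = c(rsX = 0.1)),
               "pleiotropy", class = "ivwMR_config_error")
})

test_that("in the noise-free limit the pooled estimate recovers theta", {
  theta <- 0.05
  cfg <- simulationConfig(seed = 8, trueEffect = theta,
                          nExposure = 7781e12, nCases = 6e16,
                          nControls = 1.2e17)
  st <- simulateStudy(cfg)
  p <- harmonize(selectInstruments(st$exposure, 0.999999), st$outcome)
  expect_equal(estimate(poolWithModelSelection(p)), theta,
               tolerance = 1e-4)
})

test_that("reported outcome SEs shrink as one over sqrt(n)", {
  mkSe <- function(nc, nct) {
    cfg <- simulationConfig(seed = 10, trueEffect = 0, nCases = nc,
                            nControls = nct)
    mean(assocTable(simulateStudy(cfg)$outcome)$se)
  }
  ratio <- mkSe(60801, 123504) / mkSe(2 * 60801, 2 * 123504)
  expect_equal(ratio, sqrt(2), tolerance = 0.02)
  # continuous outcomes likewise
  mkSeC <- function(n) {
    cfg <- simulationConfig(seed = 10, trueEffect = 0,
                            outcomeKind = "continuous", nOutcome = n)
    mean(assocTable(simulateStudy(cfg)$outcome)$se)
  }
  expect_equal(mkSeC(50000) / mkSeC(100000), sqrt(2), tolerance = 0.02)
})

test_that("directional pleiotropy biases the pool toward sign(alpha * E)", {
  ests <- vapply(1:200, function(s)
    estimate(simulateAndPool(s, 0, pleiotropy = c(rs964184 = 0.05))),
    numeric(1))
  expect_gt(mean(ests), 0)    # alpha > 0, E > 0: upward bias
  estsNeg <- vapply(1:200, function(s)
    estimate(simulateAndPool(s, 0, pleiotropy = c(rs964184 = -0.05))),
    numeric(1))
  expect_lt(mean(estsNeg), 0)
})

test_that("written fixtures round-trip through the reader and the pipeline", {
  dir <- withr::local_tempdir()
  cfg <- simulationConfig(seed = 6, trueEffect = 0.05)
  paths <- writeFixture(cfg, dir)
  expect_true(all(file.exists(paths)))

  st <- simulateStudy(cfg)
  exBack <- readAssociationTable(paths[["exposure"]],
                                 traitUnits = "continuous")
  outBack <- readAssociationTable(paths[["outcome"]],
                                  traitUnits = "log_odds")
  expect_equal(assocTable(exBack)$beta, assocTable(st$exposure)$beta,
               tolerance = 1e-15)
  expect_equal(assocTable(outBack)$se, assocTable(st$outcome)$se,
               tolerance = 1e-15)

  # end-to-end: pooling the files equals pooling in memory
  fromFiles <- poolWithModelSelection(
    harmonize(selectInstruments(exBack, 0.999999), outBack))
  inMemory <- poolWithModelSelection(
    harmonize(selectInstruments(st$exposure, 0.999999), st$outcome))
  expect_equal(estimate(fromFiles), estimate(inMemory), tolerance = 1e-12)
  expect_equal(stdError(fromFiles), stdError(inMemory), tolerance = 1e-12)

  # larger panels scale through
  many <- do.call(rbind, lapply(1:20, function(i) {
    s <- defaultInstrumentSnps()[rep(1, 5), ]
    s$rsid <- sprintf("rs%d_%d", i, 1:5)
    s$effect_allele <- "A"; s$other_allele <- "G"
    s
  }))
  rownames(many) <- NULL
  p100 <- writeFixture(simulationConfig(seed = 7, snps = many), dir)
  expect_equal(nrow(assocTable(readAssociationTable(p100[["exposure"]]))),
               100L)
})
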