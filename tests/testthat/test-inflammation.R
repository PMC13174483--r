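# Cytokine kinetics: half-life calibration, homeostasis, thrombin feedback.

test_that("degradation rates follow ln2 / half-life", {
  expect_equal(degradationRate(276), 2.512e-3, tolerance = 1e-3)
  expect_equal(degradationRate(3600), 1.925e-4, tolerance = 1e-3)
  k <- degradationRate(1234)
  expect_equal(log(2) / k, 1234)           # round trip
  expect_error(degradationRate(0), "positive")
})

test_that("steady-state production balances degradation exactly", {
  expect_equal(steadyStateProduction(1e-12, 1.925e-4), 1.925e-16)
  # flat trajectory at baseline
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  tr <- runInflammationPhase(bl, 86400, 0, cm)
  expect_lt(max(abs(finalState(tr) - bl) / bl), 1e-6)
  # a 2x perturbation relaxes with the configured half-life
  tr2 <- runInflammationPhase(bl * 2, 3600, 0, cm, dt = 10)
  il6 <- concentrations(tr2, "IL6")
  # after one IL-6 half-life the excess has halved
  i <- which(trajectoryTimes(tr2) == 3600)
  expect_equal((il6[i] - bl["IL6"]) / bl["IL6"], 0.5,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("pure decay recovers the configured half-lives", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  tr <- runInflammationPhase(bl, 7200, 0, cm, production_multiplier = 0,
                             dt = 1)
  times <- trajectoryTimes(tr)
  for (nm in c("IL6", "IL1B", "TNFA")) {
    series <- concentrations(tr, nm)
    t_half <- approx(series, times, xout = bl[nm] / 2)$y
    cfg <- cm@kinetics$half_life[cm@kinetics$name == nm]
    expect_lt(abs(t_half - cfg) / cfg, 0.005)
  }
})

test_that("feedback multiplier is bounded, anchored and monotone", {
  expect_equal(feedbackMultiplier(0, 4, 1e-7, 2), 1)
  m <- feedbackMultiplier(10^seq(-10, -4, by = 0.25), 4, 1e-7, 2)
  expect_true(all(diff(m) > 0))
  expect_true(all(m >= 1 & m <= 5))
  expect_equal(feedbackMultiplier(1e-2, 4, 1e-7, 2), 5, tolerance = 1e-6)
  expect_error(feedbackMultiplier(-1, 4, 1e-7, 2), ">= 0")
})

test_that("cytokine derivatives vanish at homeostasis and saturate with exposure", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  expect_equal(max(abs(cytokineRhs(bl, 0, cm))), 0)
  # at saturating exposure the IL-6 production approaches p_basal (1 + emax)
  kin <- cm@kinetics[cm@kinetics$name == "IL6", ]
  d <- cytokineRhs(bl, 1, cm)  # 1 M >> ec50
  expect_equal(unname(d["IL6"]), kin$p_basal * (1 + kin$emax) -
                 kin$k_deg * kin$baseline, tolerance = 1e-9)
  expect_error(cytokineRhs(bl * -1, 0, cm), ">= 0")
})

test_that("terminal IL-6 is nondecreasing in constant thrombin exposure", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  terminal <- vapply(c(0, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6), function(E)
    unname(finalState(runInflammationPhase(bl, 43200, E, cm))["IL6"]),
    numeric(1))
  expect_true(all(diff(terminal) >= 0))
  expect_gt(terminal[6], terminal[1])
})

test_that("cytokine model validity enforces the calibration identities", {
  expect_error(new("CytokineModel", kinetics = {
    kin <- cytokineModel()@kinetics
    kin$k_deg[1] <- kin$k_deg[1] * 2
    kin
  }), "ln2")
  expect_error(new("CytokineModel", kinetics = {
    kin <- cytokineModel()@kinetics
    kin$p_basal[2] <- kin$p_basal[2] * 1.5
    kin
  }), "steady-state")
})
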