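# Coupling laws: baseline neutrality, Hill anatomy, modulation plumbing.

test_that("TF induction is zero at baseline and half-maximal at the midpoint", {
  cp <- couplingParams()
  bl <- cytokineBaselines()
  expect_equal(tfInductionRate(bl, cp, bl), 0)

  ind <- cp@induction
  for (nm in ind$name) {
    cyt <- bl
    cyt[nm] <- bl[nm] + ind$ec50[ind$name == nm]
    expect_equal(tfInductionRate(cyt, cp, bl),
                 ind$vmax[ind$name == nm] / 2, tolerance = 1e-12)
  }
})

test_that("induction is nondecreasing along a multiplier ray", {
  cp <- couplingParams()
  bl <- cytokineBaselines()
  rate <- vapply(c(0.5, 1, 2, 5, 10, 20, 50), function(m)
    tfInductionRate(bl * m, cp, bl), numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[1], 0)  # sub-baseline levels induce nothing
})

test_that("suppression scales stay in (1 - smax, 1] and respond to the right driver", {
  cp <- couplingParams()
  bl <- cytokineBaselines()
  s0 <- suppressionScales(c(IL6 = 0, IL1B = 0, TNFA = 0), cp)
  expect_equal(unname(s0), c(1, 1), ignore_attr = TRUE)
  s <- suppressionScales(c(IL6 = 0, IL1B = 0, TNFA = 49 * bl[["TNFA"]]), cp)
  expect_lt(s[["TFPI"]], 1)
  expect_equal(s[["ATIII"]], 1)  # ATIII is IL-6-driven
  smax <- cp@suppression$smax[cp@suppression$target == "TFPI"]
  expect_gt(s[["TFPI"]], 1 - smax)
})

test_that("a baseline phase yields the neutral modulation", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  tr <- runInflammationPhase(bl, 43200, 0, cm)
  mod <- modulationFromPhase(tr, couplingParams(), bl)
  expect_equal(mod$induced_tf, 0)
  expect_equal(mod$atiii_scale, 1)
  expect_equal(mod$tfpi_scale, 1)
})

test_that("induced TF grows with exposure duration at fixed elevated cytokines", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  cp <- couplingParams()
  run <- function(hours) {
    tr <- runInflammationPhase(bl * 10, hours * 3600, 0, cm,
                               production_multiplier = 10)
    modulationFromPhase(tr, cp, bl)
  }
  m12 <- run(12); m24 <- run(24)
  expect_gt(m12$induced_tf, 0)
  expect_gte(m24$induced_tf, m12$induced_tf)
})

test_that("strong TNF-alpha elevation lowers the TFPI scale relative to baseline tone", {
  cm <- cytokineModel()
  bl <- setNames(cm@kinetics$baseline, cm@kinetics$name)
  cp <- couplingParams()
  run_mult <- function(m) {
    tone <- c(IL6 = 1, IL1B = 1, TNFA = m)
    tr <- runInflammationPhase(bl * tone, 43200, 0, cm,
                               production_multiplier = tone)
    modulationFromPhase(tr, cp, bl)
  }
  expect_lt(run_mult(50)$tfpi_scale, run_mult(1)$tfpi_scale)
})

test_that("applyModulation touches only TF, ATIII and TFPI", {
  y <- coagulationInitialState(list(tf_trigger = 5e-12))
  neutral <- applyModulation(y, list(induced_tf = 0, atiii_scale = 1,
                                     tfpi_scale = 1))
  expect_identical(neutral, y)

  mod <- applyModulation(y, list(induced_tf = 5e-12, atiii_scale = 0.5,
                                 tfpi_scale = 0.8))
  expect_equal(unname(mod["TF"]), 10e-12)
  expect_equal(unname(mod["ATIII"]), unname(y["ATIII"]) * 0.5)
  expect_equal(unname(mod["TFPI"]), unname(y["TFPI"]) * 0.8)
  untouched <- setdiff(names(y), c("TF", "ATIII", "TFPI"))
  expect_identical(mod[untouched], y[untouched])
})

test_that("fitCoupling recovers known Hill parameters from clean data", {
  dose <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64)
  resp <- 0.9 * dose^2 / (4^2 + dose^2)
  fit <- fitCoupling(dose, resp)
  expect_equal(unname(fit["top"]), 0.9, tolerance = 1e-3)
  expect_equal(unname(fit["ec50"]), 4, tolerance = 1e-3)
  expect_equal(unname(fit["hill"]), 2, tolerance = 1e-2)
  expect_lt(fit[["rss"]], 1e-8)
})
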