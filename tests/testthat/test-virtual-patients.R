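# Clinical ranges, unit resolution, LHS cohorts, window calibration.

test_that("the Normal spec midpoints reproduce the mean-plasma state", {
  dists <- resolveSpec(diseaseSpec("Normal"))
  mp <- meanPlasmaConcentrations()
  mids <- vapply(dists, function(d)
    if (d$type == "uniform") (d$lo + d$hi) / 2 else d$lo, numeric(1))
  # percent ranges are slightly asymmetric (60-130 %), so allow that skew
  expect_true(all(abs(mids[names(mp)] / mp - 1) <= 0.06))
  # cytokine rows are point masses at the configured baselines
  bl <- cytokineBaselines()
  expect_equal(mids[names(bl)], bl, ignore_attr = TRUE)
})

test_that("resolution rules produce the documented interval shapes", {
  covid <- resolveSpec(diseaseSpec("COVID19"))
  expect_equal(covid$IL6$type, "loguniform")
  expect_equal(covid$IL6$lo, toMolar(1, "pg/mL", 21000))
  expect_equal(covid$IL6$hi, toMolar(32768, "pg/mL", 21000))
  expect_equal(covid$IL1B$type, "uniform")      # zero lower bound
  expect_equal(covid$VII$lo / covid$VII$hi, 0.55 / 1.70, tolerance = 1e-12)
  expect_equal(covid$II$type, "truncnorm")
  expect_gte(covid$II$lo, 0)

  hem <- resolveSpec(diseaseSpec("HemophiliaA"))
  expect_equal(hem$VIII$lo, 0)
  expect_equal(hem$VIII$hi, 0.01 * meanPlasmaConcentrations()[["VIII"]])

  scd <- resolveSpec(diseaseSpec("SCD"))
  expect_equal(scd$X$mean, 0.66 * meanPlasmaConcentrations()[["X"]])
})

test_that("LHS places exactly one sample per equal-probability stratum", {
  spec <- diseaseSpec("Normal")
  cohort <- sampleCohort(spec, 4, seed = 9)
  d <- resolveSpec(spec)
  for (nm in c("II", "VIII")) {
    u <- (cohort[[nm]] - d[[nm]]$lo) / (d[[nm]]$hi - d[[nm]]$lo)
    expect_setequal(findInterval(u, c(0, 0.25, 0.5, 0.75, 1),
                                 rightmost.closed = TRUE), 1:4)
  }
})

test_that("cohorts are reproducible under a fixed seed and carry provenance", {
  a <- sampleCohort(diseaseSpec("SCD"), 25, seed = 77)
  b <- sampleCohort(diseaseSpec("SCD"), 25, seed = 77)
  expect_identical(a, b)
  expect_identical(attr(a, "disease"), "SCD")
  expect_identical(attr(a, "seed"), 77L)
  p <- cohortPatient(a, 3)
  expect_identical(p$sample_index, 3L)
  expect_true(all(unlist(p$factors) >= 0))
})

test_that("LHS marginals beat naive Monte Carlo in Kolmogorov-Smirnov distance", {
  # one uniform parameter; compare empirical-vs-target sup distance
  ks_unif <- function(u) max(abs(sort(u) - (seq_along(u) - 0.5) / length(u))) +
    0.5 / length(u)
  n <- 400
  wins <- 0
  for (trial in 1:20) {
    u_lhs <- cytocoag:::withr_seed(1000 + trial,
                                   as.numeric(lhs::randomLHS(n, 1)))
    u_mc <- cytocoag:::withr_seed(2000 + trial, runif(n))
    if (ks_unif(u_lhs) < ks_unif(u_mc)) wins <- wins + 1
  }
  expect_gte(wins, 18)  # >= 90 % of trials
})

test_that("calibrateCohort is a no-op when windows are already satisfied", {
  spec <- diseaseSpec("Normal")
  prcc_m <- matrix(c(0.9, -0.5, 0), nrow = 3,
                   dimnames = list(c("II", "ATIII", "dummy"), "peak_nM"))
  res <- calibrateCohort(spec, windows = list(peak_nM = c(0, 1e5)),
                         sensitivity = prcc_m, n_check = 10, max_iter = 2,
                         seed = 5)
  expect_true(res$converged)
  expect_equal(res$iterations, 1)
  expect_identical(res$spec@parameters, spec@parameters)
  expect_equal(res$fraction, 1)
})

test_that("calibrateCohort narrows ranges in the PRCC-indicated direction", {
  spec <- diseaseSpec("Normal")
  prcc_m <- matrix(c(0.9, -0.6, 0.4, 0), nrow = 4,
                   dimnames = list(c("II", "ATIII", "X", "dummy"), "peak_nM"))
  # demand higher peaks than the unmodified cohort median delivers
  res <- calibrateCohort(spec, windows = list(peak_nM = c(480, 2000)),
                         sensitivity = prcc_m, n_check = 20, max_iter = 3,
                         target_fraction = 0.9, seed = 5)
  pars0 <- diseaseSpec("Normal")@parameters
  pars1 <- res$spec@parameters
  lo0 <- pars0$lo[pars0$parameter == "II"]
  lo1 <- pars1$lo[pars1$parameter == "II"]
  expect_gt(lo1, lo0)   # II range shifted upward (positive PRCC on peak)
})

test_that("calibrateCohort reports failure on an unreachable window", {
  spec <- diseaseSpec("Normal")
  prcc_m <- matrix(c(0.9, 0), nrow = 2,
                   dimnames = list(c("II", "dummy"), "peak_nM"))
  res <- calibrateCohort(spec, windows = list(peak_nM = c(1e6, 2e6)),
                         sensitivity = prcc_m, n_check = 10, max_iter = 2,
                         seed = 5)
  expect_false(res$converged)
  expect_equal(res$fraction, 0)
  expect_true(res$diagnostics["peak_nM"] > 0)
})
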