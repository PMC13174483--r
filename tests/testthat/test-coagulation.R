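# TF-initiated cascade: construction, scenario initial states, readouts.

test_that("cascade declares symbolically exact conservation groups", {
  model <- buildCoagulationModel()
  expect_length(checkConservationSymbolic(model), 0)
  expect_setequal(names(model@conservation),
                  c("tf_total", "prothrombin_total", "atiii_total",
                    "tfpi_total"))
})

test_that("no TF trigger means no thrombin for the whole horizon", {
  tr <- runCoagulation(list(tf_trigger = 0), 1200)
  expect_lt(max(totalThrombin(tr)), 1e-12)
})

test_that("without ATIII thrombin does not decay at 25 pM TF", {
  tr <- runCoagulation("no_atiii", 1200)
  thr <- totalThrombin(tr)
  expect_gte(thr[length(thr)], 0.95 * max(thr))
  # and the TAT complex is identically zero
  expect_equal(max(atiiiIIaSeries(tr)), 0)
})

test_that("scenario initial states scale mean plasma by the multiplier map", {
  mp <- meanPlasmaConcentrations()
  y <- coagulationInitialState(list(multipliers = c(II = 1), tf_trigger = 5e-12))
  expect_equal(unname(y["II"]), unname(toMolar(100, "mg/L", 72000)),
               tolerance = 1e-2)  # 100 mg/L at 72 kDa = 1.389e-6 M
  expect_equal(unname(y["II"]), 1.4e-6)
  expect_equal(unname(y["TF"]), 5e-12)
  expect_equal(unname(y["VIIa"]), unname(mp["VIIa"]))
  complexes <- setdiff(names(y), c(cytocoag:::.coagFactors, "TF"))
  expect_true(all(y[complexes] == 0))

  y0 <- coagulationInitialState(list(multipliers = c(ATIII = 0),
                                     tf_trigger = 25e-12))
  expect_equal(unname(y0["ATIII"]), 0)
  expect_error(coagulationInitialState(list(multipliers = c(II = -1),
                                            tf_trigger = 5e-12)), ">= 0")

  pro <- perturbationScenario("procoagulant_dominant")
  expect_equal(unname(pro$multipliers[c("II", "V", "VIII", "IX", "X")]),
               rep(1.5, 5))
  expect_equal(unname(pro$multipliers[c("ATIII", "TFPI")]), rep(0.5, 2))
  expect_equal(pro$tf_trigger, 5e-12)
})

test_that("total thrombin weights meizothrombin and peaks in the interior", {
  tr <- runCoagulation("baseline25", 1200)
  iia <- concentrations(tr, "IIa"); miia <- concentrations(tr, "mIIa")
  expect_equal(totalThrombin(tr), iia + 1.2 * miia)
  expect_equal(totalThrombin(tr, w = 2), iia + 2 * miia)
  thr <- totalThrombin(tr)
  i <- which.max(thr)
  expect_gt(i, 1); expect_lt(i, length(thr))       # rises then falls
  expect_lt(thr[length(thr)], 0.5 * thr[i])        # clear decay phase
})

test_that("ATIII-IIa accumulates monotonically to a positive plateau", {
  tr <- runCoagulation("mean_plasma_5pM", 1200)
  tat <- atiiiIIaSeries(tr)
  expect_gt(tat[length(tat)], 0)
  expect_true(all(diff(tat) >= -1e-6 * max(tat)))
  # refining solver tolerances moves the final value by < 0.1 %
  tr2 <- runCoagulation("mean_plasma_5pM", 1200, rtol = 1e-9, atol = 1e-13)
  tat2 <- atiiiIIaSeries(tr2)
  expect_lt(abs(tat[length(tat)] - tat2[length(tat2)]) / tat2[length(tat2)],
            1e-3)
})

test_that("no species dips below minus ten times the absolute tolerance", {
  for (sc in c("baseline25", "no_atiii_tfpi", "mean_plasma_5pM",
               "procoagulant_dominant", "anticoagulant_dominant")) {
    tr <- runCoagulation(sc, 1200)
    expect_gt(min(tr@concentrations), -1e-11)
  }
})

test_that("unit conversion is exact and rejects unknown units", {
  expect_equal(toMolar(100, "mg/L", 72000), 100e-3 / 72000)
  expect_equal(toMolar(70, "ng/mL", 40000), 1.75e-9)
  expect_equal(toMolar(0, "pg/mL", 17000), 0)
  expect_error(toMolar(1, "furlongs", 1000), "unknown unit")
  expect_error(toMolar(-1, "mg/L", 1000), ">= 0")
})
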