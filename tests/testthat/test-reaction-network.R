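# Generic mass-action engine: derivative assembly, stiff integration,
# conservation checking, serialization.

toy_decay <- function(k = 0.1) makeFixture("toy_network", list(kind = "decay", k = k))
toy_bimol <- function() makeFixture("toy_network", list(kind = "bimolecular"))

test_that("buildRhs assembles mass-action terms for the basic motifs", {
  f <- buildRhs(toy_decay(0.1))
  d <- f(0, c(A = 1, B = 0))
  expect_equal(unname(d["A"]), -0.1)
  expect_equal(unname(d["B"]), +0.1)

  empty <- reactionNetwork(data.frame(name = "A", initial = 1), list())
  expect_equal(unname(buildRhs(empty)(0, c(A = 5))), 0)

  bim <- reactionNetwork(
    data.frame(name = c("A", "B", "C"), initial = c(1e-6, 1e-6, 0)),
    list(reaction(c("A", "B"), "C", k = 1e6)))
  d <- buildRhs(bim)(0, c(A = 1e-6, B = 1e-6, C = 0))
  expect_equal(unname(d["C"]), 1e-6)
  expect_equal(unname(d["A"]), -1e-6)
})

test_that("derivative equals stoichiometry matrix times rate vector on random states", {
  model <- toy_bimol()
  f <- buildRhs(model)
  S <- cytocoag:::stoichiometryMatrix(model)
  set.seed(42)
  for (i in 1:100) {
    y <- runif(3, 0, 2e-6)
    names(y) <- speciesNames(model)
    v <- c(1e6 * y["A"] * y["B"], 0.05 * y["C"])
    expect_equal(unname(f(0, y)), unname(as.numeric(S %*% v)), tolerance = 1e-12)
  }
})

test_that("reaction networks validate species, molecularity and conservation", {
  expect_error(reactionNetwork(data.frame(name = "A", initial = 1),
                               list(reaction("A", "Z", k = 1))),
               "unknown species")
  expect_error(reactionNetwork(data.frame(name = c("A", "A"), initial = c(1, 1)),
                               list()),
               "unique")
  expect_error(reactionNetwork(data.frame(name = c("A", "B", "C"),
                                          initial = c(1, 1, 0)),
                               list(reaction(c("A", "A", "B"), "C", k = 1))),
               "molecularity")
  # a group the stoichiometry does not conserve is rejected at construction
  expect_error(reactionNetwork(data.frame(name = c("A", "B"), initial = c(1, 0)),
                               list(reaction("A", c("B", "B"), k = 1)),
                               conservation = list(total = c(A = 1, B = 1))),
               "not invariant")
})

test_that("simulate matches the closed-form exponential and the t_span = 0 identity", {
  k <- 0.07
  tr <- simulateNetwork(toy_decay(k), 60, dt = 1)
  expect_lt(max(abs(concentrations(tr, "A") -
                    1e-6 * exp(-k * trajectoryTimes(tr)))) / 1e-6, 1e-5)
  expect_equal(tr@concentrations[1, ], initialState(toy_decay(k)))

  tr0 <- simulateNetwork(toy_decay(k), 0)
  expect_identical(trajectoryTimes(tr0), 0)
  expect_equal(tr0@concentrations[1, ], initialState(toy_decay(k)))
})

test_that("stiff solver agrees with a fine-step RK4 oracle on a bimolecular network", {
  model <- toy_bimol()
  f <- buildRhs(model)
  tr <- simulateNetwork(model, 10, dt = 1, rtol = 1e-10, atol = 1e-16)
  oracle <- rk4_integrate(function(t, y) f(t, y), initialState(model),
                          10, dt = 1e-3)
  final <- finalState(tr)
  expect_lt(max(abs(final - oracle) / pmax(abs(oracle), 1e-12)), 1e-4)
})

test_that("tolerance refinement changes reported concentrations by < 0.1 %", {
  model <- toy_bimol()
  a <- finalState(simulateNetwork(model, 20, rtol = 1e-8, atol = 1e-12))
  b <- finalState(simulateNetwork(model, 20, rtol = 1e-9, atol = 1e-13))
  # relative to the concentration scale of the system (species that are
  # numerically exhausted carry no meaningful relative error)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-3)
})

test_that("conservation check reports drift per group and flags non-conserved sums", {
  model <- reactionNetwork(
    data.frame(name = c("A", "B"), initial = c(1e-6, 2e-7)),
    list(reaction("A", "B", k = 0.05), reaction("B", "A", k = 0.02)),
    conservation = list(total = c(A = 1, B = 1)))
  tr <- simulateNetwork(model, 100)
  expect_lt(checkConservation(tr, model)["total"], 1e-8)

  # a group over a produced species drifts visibly but is not an error
  open_model <- reactionNetwork(
    data.frame(name = c("S", "P"), initial = c(1e-6, 0)),
    list(reaction("S", c("P", "P"), k = 0.05)))
  tr2 <- simulateNetwork(open_model, 100)
  open_model@conservation <- list(p_only = c(P = 1))
  drift <- suppressWarnings(checkConservation(tr2, open_model))
  expect_true(drift["p_only"] > 1 || is.infinite(drift["p_only"]))

  expect_error(checkConservation(tr, model2 <- {
    m <- model; m@conservation <- list(bad = c(Q = 1)); m
  }), "absent")
})

test_that("JSON serialization round-trips a network exactly", {
  model <- toy_bimol()
  path <- withr::local_tempfile(fileext = ".json")
  networkToJSON(model, path)
  back <- networkFromJSON(path)
  expect_equal(back@species$name, model@species$name)
  expect_equal(back@species$initial, model@species$initial)
  expect_equal(lapply(back@reactions, `[`, c("reactants", "products", "k")),
               lapply(model@reactions, `[`, c("reactants", "products", "k")))
  expect_equal(back@conservation, model@conservation)
})

test_that("trajectory CSV uses the time_s header convention", {
  tr <- simulateNetwork(toy_decay(), 5)
  path <- withr::local_tempfile(fileext = ".csv")
  trajectoryToCSV(tr, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "\"time_s\",\"A\",\"B\"")
})
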