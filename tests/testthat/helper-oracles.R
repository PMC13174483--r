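# Independent oracles and shared fixtures for the test suite.

# Fixed-step classic Runge-Kutta integrator, independent of deSolve.
rk4_integrate <- function(f, y0, t_end, dt) {
  n <- ceiling(t_end / dt)
  y <- y0
  t <- 0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# Composite Simpson integral on a uniform grid (odd number of points).
simpson_integral <- function(x, y) {
  n <- length(x)
  if (n %% 2 == 0) { n <- n - 1; x <- x[1:n]; y <- y[1:n] }
  h <- x[2] - x[1]
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
           2 * sum(y[seq(3, n - 2, by = 2)]))
}

# PRCC by explicit normal-equations residualisation, independent of
# lm.fit / cor.
prcc_oracle <- function(X, y) {
  R <- apply(as.matrix(X), 2, rank)
  ry <- rank(y)
  out <- numeric(ncol(R))
  for (j in seq_len(ncol(R))) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    beta_x <- solve(t(Z) %*% Z, t(Z) %*% R[, j])
    beta_y <- solve(t(Z) %*% Z, t(Z) %*% ry)
    ex <- R[, j] - Z %*% beta_x
    ey <- ry - Z %*% beta_y
    out[j] <- sum((ex - mean(ex)) * (ey - mean(ey))) /
      sqrt(sum((ex - mean(ex))^2) * sum((ey - mean(ey))^2))
  }
  setNames(out, colnames(R))
}

# Lazily computed expensive shared runs (one per session).
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

baseline_two_phase <- function() {
  cached("baseline_two_phase", runTwoPhase(referencePatient()))
}

standard_dose_scan <- function() {
  cached("dose_scan", doseScan())
}

cohort_metrics <- function(disease, inflamed = FALSE, n = 200) {
  key <- paste0("cohort_", disease, "_", inflamed, "_", n)
  cached(key, {
    cohort <- cached(paste0("cohort_", disease, "_", n),
                     sampleCohort(diseaseSpec(disease), n, seed = 1))
    cohortTG(cohort, inflamed = inflamed)
  })
}
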