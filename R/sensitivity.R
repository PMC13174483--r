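# Global sensitivity analysis: Latin hypercube sampling over a disease
# spec plus a dummy control parameter, with partial rank correlation
# coefficients (PRCC) between each input and each TG metric.

#' Partial rank correlation coefficients
#'
#' Rank-transforms every column of X and y (average ranks for ties); for
#' each parameter j, the PRCC is the Pearson correlation between the
#' residuals of ranked x_j and of ranked y after each is linearly
#' regressed (with intercept) on all the other ranked parameters. A
#' constant column cannot be ranked meaningfully; its PRCC is returned as
#' NA with a warning.
#'
#' @param X numeric matrix or data.frame, samples by parameters (needs at
#'   least parameters + 2 rows).
#' @param y numeric response vector.
#' @return named numeric vector of PRCCs in [-1, 1] (NA for degenerate
#'   columns).
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X and y must have matching sample counts")
  if (nrow(X) < ncol(X) + 2)
    stop("need at least parameters + 2 samples for PRCC")
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    warning("constant parameter column(s), PRCC undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    if (const[j]) next
    others <- R[, -j, drop = FALSE]
    others <- others[, !const[-j], drop = FALSE]
    Z <- cbind(1, others)
    rx_res <- stats::lm.fit(Z, R[, j])$residuals
    ry_res <- stats::lm.fit(Z, ry)$residuals
    out[j] <- stats::cor(rx_res, ry_res)
  }
  out
}

#' LHS-PRCC sensitivity of TG metrics over a disease spec
#'
#' Draws an LHS sample of patient parameter sets from the disease spec,
#' appends a dummy parameter (uniform on [0, 1], disconnected from the
#' model) as a null control, simulates each patient through the two-phase
#' protocol, and computes the PRCC of every parameter against each TG
#' metric. Fully reproducible under the seed. Failed simulations are
#' dropped with a message; the run aborts if more than 1 percent fail.
#'
#' @param spec a [DiseaseSpec-class].
#' @param n number of LHS samples (the reference design uses 5000;
#'   the default 200 keeps routine runs fast).
#' @param protocol a [PhaseProtocol-class].
#' @param cytokine_model,coupling models for the two-phase run.
#' @param inflamed include the inflammation preconditioning phase
#'   (default TRUE; cytokine parameters only influence the metrics through
#'   it).
#' @param seed integer RNG seed.
#' @param metrics which TG metrics to analyse.
#' @param ... solver options.
#' @return a [SensitivityResult-class]
#' @export
runSensitivity <- function(spec, n = 200, protocol = phaseProtocol(),
                           cytokine_model = cytokineModel(),
                           coupling = couplingParams(), inflamed = TRUE,
                           seed = 1L,
                           metrics = c("peak_nM", "ttp_s", "lag_s",
                                       "etp_nM_s"), ...) {
  cohort <- sampleCohort(spec, n, seed = seed,
                         baselines = setNames(cytokine_model@kinetics$baseline,
                                              cytokine_model@kinetics$name))
  dummy <- withr_seed(seed + 1L, as.numeric(lhs::randomLHS(n, 1)))
  results <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    results[[i]] <- tryCatch({
      patient <- cohortPatient(cohort, i)
      if (inflamed) {
        res <- runTwoPhase(patient, protocol, cytokine_model, coupling, ...)
        tgMetricsAsRecord(res$metrics)
      } else {
        traj <- simulateNetwork(coagulationModelCache(),
                                protocol@coag_duration,
                                y0 = patientInitialState(patient,
                                                         protocol@tf_trigger),
                                ...)
        tgMetricsAsRecord(computeTGMetrics(trajectoryTimes(traj),
                                           totalThrombin(traj)))
      }
    }, error = function(e) { failed[i] <<- TRUE; NULL })
  }
  n_failed <- sum(failed)
  if (n_failed > 0.01 * n)
    stop(n_failed, " of ", n, " simulations failed (> 1%); aborting")
  if (n_failed) message(n_failed, " failed simulation(s) dropped")
  keep <- !failed
  mets <- do.call(rbind, results[keep])
  X <- cbind(as.matrix(cohort), dummy = dummy)[keep, , drop = FALSE]
  metrics <- intersect(metrics, colnames(mets))
  pr <- sapply(metrics, function(mc) suppressWarnings(prcc(X, mets[[mc]])))
  res <- new("SensitivityResult",
             prcc = matrix(pr, nrow = ncol(X),
                           dimnames = list(colnames(X), metrics)),
             n_samples = as.integer(sum(keep)),
             n_failed = as.integer(n_failed),
             seed = as.integer(seed), disease = spec@disease)
  res
}

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult (%s, n = %d, seed = %d, %d failed)\n",
              object@disease, object@n_samples, object@seed, object@n_failed))
  print(round(object@prcc, 3))
})

#' Long-format view of a sensitivity result
#'
#' @param result a [SensitivityResult-class]
#' @return data.frame with columns \code{parameter}, \code{metric},
#'   \code{prcc}.
#' @export
sensitivityAsRecord <- function(result) {
  m <- result@prcc
  data.frame(parameter = rep(rownames(m), ncol(m)),
             metric = rep(colnames(m), each = nrow(m)),
             prcc = as.numeric(m), stringsAsFactors = FALSE)
}
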