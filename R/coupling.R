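# Coupling laws: phenomenological Hill-type input-output relationships
# linking cytokine excess over baseline to (i) tissue factor induction and
# (ii) suppression of the anticoagulants ATIII (by IL-6) and TFPI (by
# TNF-alpha). Excess (C - baseline), not absolute concentration, drives
# the coupling so that homeostasis is exactly neutral.

#' Construct coupling parameters
#'
#' Defaults are expressed per cytokine in multiples of its baseline (the
#' calibration data behind these laws are normalised fold-changes): the
#' induction and suppression midpoints sit at 20 baseline-equivalents of
#' excess with Hill coefficient 2, which makes the 1x and 2x inflammatory
#' states nearly neutral while the response between 10x and 50x rises
#' steeply. All parameters are plain configuration and re-fittable with
#' [fitCoupling()].
#'
#' @param baselines named cytokine baselines (mol/L) used to convert the
#'   fold-based defaults into molar midpoints.
#' @param vmax named mol/(L s) maximal TF induction rates per cytokine.
#' @param ec50_fold named induction midpoints, in multiples of baseline
#'   excess.
#' @param hill named induction Hill coefficients.
#' @param smax named maximal fractional suppression for \code{ATIII} and
#'   \code{TFPI}, each in [0, 1).
#' @param sup_ec50_fold,sup_hill suppression midpoints (baseline multiples
#'   of the driver's excess) and Hill coefficients.
#' @param tf_clearance_halflife seconds; first-order decay of induced TF so
#'   transient inflammation does not permanently raise it (default 6 h).
#' @return a [CouplingParams-class]
#' @export
couplingParams <- function(baselines = cytokineBaselines(),
                           vmax = c(IL6 = 3e-16, IL1B = 2e-17, TNFA = 4e-17),
                           ec50_fold = c(IL6 = 100, IL1B = 20, TNFA = 20),
                           hill = c(IL6 = 2, IL1B = 2, TNFA = 1),
                           smax = c(ATIII = 0.5, TFPI = 0.2),
                           sup_ec50_fold = c(ATIII = 100, TFPI = 20),
                           sup_hill = c(ATIII = 2, TFPI = 2),
                           tf_clearance_halflife = 21600) {
  nm <- c("IL6", "IL1B", "TNFA")
  induction <- data.frame(
    name = nm, vmax = as.numeric(vmax[nm]),
    ec50 = as.numeric(ec50_fold[nm] * baselines[nm]),
    hill = as.numeric(hill[nm]), stringsAsFactors = FALSE)
  drivers <- c(ATIII = "IL6", TFPI = "TNFA")
  suppression <- data.frame(
    target = names(drivers), driver = unname(drivers),
    smax = as.numeric(smax[names(drivers)]),
    ec50 = as.numeric(sup_ec50_fold[names(drivers)] * baselines[drivers]),
    hill = as.numeric(sup_hill[names(drivers)]), stringsAsFactors = FALSE)
  new("CouplingParams", induction = induction, suppression = suppression,
      tf_clearance_halflife = tf_clearance_halflife)
}

setMethod("show", "CouplingParams", function(object) {
  cat("CouplingParams:\n  TF induction (vmax mol/L/s @ ec50 M):\n")
  ind <- object@induction
  for (i in seq_len(nrow(ind)))
    cat(sprintf("    %-4s vmax %.3g, ec50 %.3g, hill %g\n",
                ind$name[i], ind$vmax[i], ind$ec50[i], ind$hill[i]))
  sup <- object@suppression
  cat("  anticoagulant suppression:\n")
  for (i in seq_len(nrow(sup)))
    cat(sprintf("    %s <- %s: smax %.2f, ec50 %.3g, hill %g\n",
                sup$target[i], sup$driver[i], sup$smax[i], sup$ec50[i],
                sup$hill[i]))
})

#' Instantaneous TF induction rate from cytokine levels
#'
#' Sum over cytokines of \code{vmax Ce^h / (ec50^h + Ce^h)} where
#' \code{Ce = max(C - baseline, 0)} is the excess over the homeostatic
#' level; exactly zero when every cytokine sits at baseline.
#'
#' @param cytokines named mol/L vector over IL6, IL1B, TNFA.
#' @param params a [CouplingParams-class].
#' @param baselines named cytokine baselines (mol/L).
#' @return mol/(L s) induction rate.
#' @export
tfInductionRate <- function(cytokines, params,
                            baselines = cytokineBaselines()) {
  ind <- params@induction
  if (any(cytokines[ind$name] < 0)) stop("cytokine levels must be >= 0")
  ce <- pmax(as.numeric(cytokines[ind$name]) -
             as.numeric(baselines[ind$name]), 0)
  sum(ind$vmax * ce^ind$hill / (ind$ec50^ind$hill + ce^ind$hill))
}

#' Anticoagulant suppression scales from cytokine excess
#'
#' \code{s(Ce) = 1 - smax Ce^h / (ec50^h + Ce^h)}, one scale per target,
#' evaluated at the supplied excess of the target's driver cytokine.
#'
#' @param excess named nonnegative excess (mol/L) per cytokine.
#' @param params a [CouplingParams-class].
#' @return named vector with elements \code{ATIII} and \code{TFPI}, each in
#'   \code{(1 - smax, 1]}.
#' @export
suppressionScales <- function(excess, params) {
  sup <- params@suppression
  ce <- pmax(as.numeric(excess[sup$driver]), 0)
  s <- 1 - sup$smax * ce^sup$hill / (sup$ec50^sup$hill + ce^sup$hill)
  setNames(s, sup$target)
}

#' Summarise an inflammation phase into a coagulation modulation
#'
#' Induced TF is the integral of the instantaneous induction rate along
#' the cytokine trajectory under first-order clearance of the induced
#' pool (solved interval-by-interval with the exact exponential
#' propagator). The ATIII and TFPI scales are the suppression Hill laws
#' evaluated at the time-averaged cytokine excess over the phase.
#' Deterministic; a trajectory that never leaves baseline yields the
#' neutral modulation (induced_tf = 0, both scales = 1).
#'
#' @param cytokine_trajectory a [Trajectory-class] from
#'   [runInflammationPhase()].
#' @param params a [CouplingParams-class].
#' @param baselines named cytokine baselines (mol/L).
#' @param init_induced_tf mol/L of induced TF already present at phase
#'   start (default 0).
#' @return list with \code{induced_tf} (mol/L), \code{atiii_scale} and
#'   \code{tfpi_scale} (each in (0, 1]).
#' @export
modulationFromPhase <- function(cytokine_trajectory, params,
                                baselines = cytokineBaselines(),
                                init_induced_tf = 0) {
  times <- cytokine_trajectory@times
  conc <- cytokine_trajectory@concentrations
  kc <- log(2) / params@tf_clearance_halflife
  rate <- vapply(seq_along(times), function(i)
    tfInductionRate(conc[i, ], params, baselines), numeric(1))
  tf <- init_induced_tf
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    rbar <- (rate[i] + rate[i + 1L]) / 2
    tf <- tf * exp(-kc * dt) + rbar * (1 - exp(-kc * dt)) / kc
  }
  # time-averaged excess per cytokine (trapezoidal mean)
  horizon <- times[length(times)] - times[1]
  avg_excess <- vapply(colnames(conc), function(nm) {
    ex <- pmax(conc[, nm] - baselines[nm], 0)
    sum(diff(times) * (ex[-1] + ex[-length(ex)]) / 2) / horizon
  }, numeric(1))
  s <- suppressionScales(avg_excess, params)
  list(induced_tf = tf, atiii_scale = unname(s["ATIII"]),
       tfpi_scale = unname(s["TFPI"]))
}

#' Apply an inflammatory modulation to a coagulation initial state
#'
#' Adds the induced TF to the trigger and scales initial anticoagulant
#' availability; every other factor is untouched (factor concentrations
#' are restored to their reference values between cycles).
#'
#' @param state named coagulation initial-state vector (mol/L).
#' @param mod list from [modulationFromPhase()].
#' @return modulated state vector.
#' @export
applyModulation <- function(state, mod) {
  stopifnot(mod$induced_tf >= 0, mod$atiii_scale > 0, mod$atiii_scale <= 1,
            mod$tfpi_scale > 0, mod$tfpi_scale <= 1)
  state["TF"] <- state["TF"] + mod$induced_tf
  state["ATIII"] <- state["ATIII"] * mod$atiii_scale
  state["TFPI"] <- state["TFPI"] * mod$tfpi_scale
  state
}

#' Least-squares Hill fit for coupling calibration data
#'
#' Fits \code{y = top x^h / (ec50^h + x^h)} to a two-column dose-response
#' table (dose, normalised response) by Nelder-Mead least squares on log
#' parameters. Intended for re-fitting the coupling blocks against
#' user-supplied digitised measurements; no such data ships with the
#' package.
#'
#' @param dose,response numeric vectors (dose >= 0).
#' @param start optional named starting values \code{c(top, ec50, hill)}.
#' @return named vector \code{c(top, ec50, hill, rss)}.
#' @export
fitCoupling <- function(dose, response, start = NULL) {
  stopifnot(length(dose) == length(response), all(dose >= 0))
  if (is.null(start))
    start <- c(top = max(response), ec50 = stats::median(dose[dose > 0]),
               hill = 1.5)
  obj <- function(p) {
    top <- exp(p[1]); ec50 <- exp(p[2]); h <- 1 + exp(p[3])
    pred <- top * dose^h / (ec50^h + dose^h)
    sum((pred - response)^2)
  }
  fit <- stats::optim(c(log(start[["top"]]), log(start[["ec50"]]),
                        log(max(start[["hill"]] - 1, 1e-3))), obj,
                      control = list(maxit = 2000, reltol = 1e-12))
  c(top = exp(fit$par[1]), ec50 = exp(fit$par[2]), hill = 1 + exp(fit$par[3]),
    rss = fit$value)
}
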