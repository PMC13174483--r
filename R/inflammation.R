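# Cytokine kinetics: first-order degradation calibrated from plasma
# half-lives, production calibrated by a steady-state (homeostasis)
# constraint, and thrombin-driven amplification of production.

#' First-order degradation rate from a plasma half-life
#'
#' @param half_life seconds, > 0.
#' @return rate in 1/s, \code{ln 2 / half_life}.
#' @examples
#' degradationRate(276)   # TNF-alpha, 4.6 min half-life
#' degradationRate(3600)  # IL-6 / IL-1beta, ~1 h half-life
#' @export
degradationRate <- function(half_life) {
  if (any(half_life <= 0)) stop("half-life must be positive")
  log(2) / half_life
}

#' Steady-state production rate for a degrading species
#'
#' The production that holds a species at its normal plasma concentration
#' under first-order clearance: \code{p = k_deg * baseline}.
#'
#' @param baseline_conc mol/L, > 0.
#' @param k_deg 1/s, > 0.
#' @return production rate in mol/(L s).
#' @export
steadyStateProduction <- function(baseline_conc, k_deg) {
  if (any(baseline_conc <= 0) || any(k_deg <= 0))
    stop("baseline concentration and degradation rate must be positive")
  k_deg * baseline_conc
}

#' Default cytokine baseline concentrations
#'
#' Normal plasma cytokine levels are not part of the clinical ranges table
#' (its Normal column is empty for cytokines); these defaults are typical
#' healthy-plasma values (IL-6 ~2 pg/mL, TNF-alpha ~2 pg/mL,
#' IL-1beta ~0.2 pg/mL) converted to mol/L with [molecularWeights()], and
#' are configurable. Every shipped analysis is expressed relative to these
#' baselines, never in absolute pg/mL.
#'
#' @return named mol/L vector over IL6, IL1B, TNFA.
#' @export
cytokineBaselines <- function() {
  mw <- molecularWeights()
  c(IL6 = unname(toMolar(2, "pg/mL", mw["IL6"])),
    IL1B = unname(toMolar(0.2, "pg/mL", mw["IL1B"])),
    TNFA = unname(toMolar(2, "pg/mL", mw["TNFA"])))
}

#' Build the cytokine kinetics model
#'
#' Half-life defaults: IL-6 and IL-1beta 3600 s, TNF-alpha 276 s (4.6 min).
#' Thrombin feedback applies to IL-6 and TNF-alpha by default; IL-1beta
#' feedback ships disabled (emax = 0) but is configurable. Feedback
#' defaults give roughly 2 to 5-fold induction at peak physiological
#' thrombin exposure (~100 nM time-averaged).
#'
#' @param half_lives named seconds vector over IL6, IL1B, TNFA.
#' @param baselines named mol/L vector (default [cytokineBaselines()]).
#' @param emax,ec50,hill named feedback Hill parameters per cytokine;
#'   \code{ec50} in mol/L of thrombin exposure.
#' @return a [CytokineModel-class]
#' @export
cytokineModel <- function(half_lives = c(IL6 = 3600, IL1B = 3600, TNFA = 276),
                          baselines = cytokineBaselines(),
                          emax = c(IL6 = 4, IL1B = 0, TNFA = 4),
                          ec50 = c(IL6 = 1e-7, IL1B = 1e-7, TNFA = 1e-7),
                          hill = c(IL6 = 2, IL1B = 2, TNFA = 2)) {
  nm <- c("IL6", "IL1B", "TNFA")
  k <- degradationRate(half_lives[nm])
  kin <- data.frame(
    name = nm,
    half_life = as.numeric(half_lives[nm]),
    k_deg = as.numeric(k),
    baseline = as.numeric(baselines[nm]),
    p_basal = as.numeric(steadyStateProduction(baselines[nm], k)),
    emax = as.numeric(emax[nm]), ec50 = as.numeric(ec50[nm]),
    hill = as.numeric(hill[nm]), stringsAsFactors = FALSE)
  new("CytokineModel", kinetics = kin)
}

setMethod("show", "CytokineModel", function(object) {
  kin <- object@kinetics
  cat("CytokineModel:\n")
  for (i in seq_len(nrow(kin)))
    cat(sprintf("  %-4s half-life %5.0f s, baseline %.3g M, feedback emax %.3g\n",
                kin$name[i], kin$half_life[i], kin$baseline[i], kin$emax[i]))
})

#' Thrombin feedback multiplier on cytokine production
#'
#' \code{m(E) = 1 + emax E^h / (ec50^h + E^h)}: equals 1 with no exposure,
#' saturates at \code{1 + emax}, and is nondecreasing in E.
#'
#' @param exposure thrombin exposure E (mol/L-equivalent, >= 0).
#' @param emax,ec50,hill Hill parameters.
#' @return multiplier in [1, 1 + emax].
#' @export
feedbackMultiplier <- function(exposure, emax, ec50, hill) {
  if (any(exposure < 0)) stop("exposure must be >= 0")
  1 + emax * exposure^hill / (ec50^hill + exposure^hill)
}

#' Cytokine derivative field
#'
#' \code{dC/dt = p_basal * production_multiplier * m(E) - k_deg * C} per
#' cytokine. \code{production_multiplier} scales basal production and is
#' how sustained inflammatory states (production held at a fold-elevated
#' level) are represented.
#'
#' @param state named mol/L vector over IL6, IL1B, TNFA (>= 0).
#' @param thrombin_exposure scalar exposure E (mol/L-equivalent).
#' @param model a [CytokineModel-class].
#' @param production_multiplier named or scalar fold-scaling of basal
#'   production (default 1 = homeostasis).
#' @return named derivative vector, mol/(L s).
#' @export
cytokineRhs <- function(state, thrombin_exposure, model,
                        production_multiplier = 1) {
  kin <- model@kinetics
  if (any(state[kin$name] < 0)) stop("cytokine state must be >= 0")
  pm <- rep_len(production_multiplier, nrow(kin))
  if (!is.null(names(production_multiplier)))
    pm <- production_multiplier[kin$name]
  m <- feedbackMultiplier(thrombin_exposure, kin$emax, kin$ec50, kin$hill)
  d <- kin$p_basal * pm * m - kin$k_deg * state[kin$name]
  setNames(as.numeric(d), kin$name)
}

#' Run an inflammation phase
#'
#' Integrates the cytokine kinetics for \code{duration} seconds at a 60 s
#' reporting step, under a constant thrombin exposure carried over from the
#' preceding coagulation phase (the two subsystems are deliberately
#' phase-split: coagulation resolves in seconds to minutes, cytokine
#' modulation over hours).
#'
#' @param initial named mol/L vector over IL6, IL1B, TNFA.
#' @param duration seconds, > 0.
#' @param thrombin_exposure constant exposure E for the whole phase.
#' @param model a [CytokineModel-class].
#' @param production_multiplier see [cytokineRhs()].
#' @param dt reporting step, seconds.
#' @return a [Trajectory-class] over the three cytokines.
#' @export
runInflammationPhase <- function(initial, duration, thrombin_exposure = 0,
                                 model = cytokineModel(),
                                 production_multiplier = 1, dt = 60) {
  if (duration <= 0) stop("duration must be positive")
  kin <- model@kinetics
  y0 <- setNames(as.numeric(initial[kin$name]), kin$name)
  if (anyNA(y0)) stop("initial state must name IL6, IL1B, TNFA")
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  out <- deSolve::ode(y = y0, times = times,
    func = function(t, y, p)
      list(cytokineRhs(y, thrombin_exposure, model, production_multiplier)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-20)
  new("Trajectory", times = as.numeric(out[, 1]),
      concentrations = matrix(out[, -1], nrow = nrow(out),
                              dimnames = list(NULL, kin$name)))
}
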