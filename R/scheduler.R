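# Two-phase scheduler: an hours-scale inflammation phase sets the TF /
# ATIII / TFPI conditions, then a seconds-scale coagulation phase runs the
# cascade; iterated to model the thromboinflammatory amplification loop.

#' Construct a phase protocol
#'
#' @param inflam_duration inflammation preconditioning, seconds
#'   (presets 12 h = 43200 and 24 h = 86400; default 12 h).
#' @param coag_duration coagulation module horizon, seconds (default 1200).
#' @param tf_trigger TF trigger, mol/L (default 5 pM).
#' @param n_cycles number of inflammation-coagulation cycles (default 1;
#'   the multi-cycle amplification preset uses 5).
#' @param exposure_metric how a coagulation phase is summarised into the
#'   thrombin exposure fed to the next inflammation phase: \code{"ETP"}
#'   (ETP / horizon, i.e. time-averaged thrombin) or \code{"peak"}.
#' @param exposure_gain dimensionless rescaling of the metric into the
#'   feedback law's concentration units (0 silences the feedback channel).
#' @return a [PhaseProtocol-class]
#' @export
phaseProtocol <- function(inflam_duration = 43200, coag_duration = 1200,
                          tf_trigger = 5e-12, n_cycles = 1L,
                          exposure_metric = c("ETP", "peak"),
                          exposure_gain = 1) {
  new("PhaseProtocol", inflam_duration = inflam_duration,
      coag_duration = coag_duration, tf_trigger = tf_trigger,
      n_cycles = as.integer(n_cycles),
      exposure_metric = match.arg(exposure_metric),
      exposure_gain = exposure_gain)
}

setMethod("show", "PhaseProtocol", function(object) {
  cat(sprintf(paste0("PhaseProtocol: %g h inflammation + %g s coagulation, ",
                     "TF %g pM, %d cycle(s), exposure = %s x %g\n"),
              object@inflam_duration / 3600, object@coag_duration,
              object@tf_trigger * 1e12, object@n_cycles,
              object@exposure_metric, object@exposure_gain))
})

#' Initial coagulation state for a virtual patient
#'
#' Zymogens and inhibitors at the patient's sampled concentrations, VIIa at
#' its sampled trace level, TF at the trigger, complexes at zero.
#'
#' @param patient a patient list from [virtualPatient()].
#' @param tf_trigger mol/L.
#' @return named state vector over all cascade species.
#' @export
patientInitialState <- function(patient, tf_trigger) {
  y <- initialState(coagulationModelCache())
  fx <- patient$factors
  unknown <- setdiff(names(fx), names(y))
  if (length(unknown))
    stop("patient carries unknown factors: ", paste(unknown, collapse = ", "))
  y[names(fx)] <- fx
  y["TF"] <- tf_trigger
  y
}

#' Run one inflammation-then-coagulation cycle
#'
#' The inflammation phase runs at the patient's cytokine tone (production
#' held so that, absent thrombin feedback, levels stay at the patient's
#' sampled concentrations) under the carried-over thrombin exposure; the
#' resulting modulation (induced TF, ATIII/TFPI scaling) is applied to the
#' patient's coagulation initial state; the cascade then runs for the
#' coagulation horizon. Deterministic: repeated calls are bit-identical.
#'
#' @param patient a patient list from [virtualPatient()].
#' @param protocol a [PhaseProtocol-class].
#' @param cytokine_model a [CytokineModel-class].
#' @param coupling a [CouplingParams-class].
#' @param enable_coupling if FALSE the neutral modulation is applied and
#'   the result equals the bare coagulation run of the same patient.
#' @param exposure_in thrombin exposure from the previous cycle
#'   (0 for a cold start).
#' @param cytokine_init optional cytokine state carried over from a
#'   previous cycle (defaults to the patient's sampled levels).
#' @param cycle_index bookkeeping label.
#' @param ... solver options passed to [simulateNetwork()].
#' @return list with \code{cycle_index}, \code{cytokine_trajectory},
#'   \code{coagulation_trajectory}, \code{metrics} ([TGMetrics-class]),
#'   \code{atiii_iia_final} (mol/L), \code{modulation}, and
#'   \code{exposure_out}.
#' @export
runTwoPhase <- function(patient, protocol = phaseProtocol(),
                        cytokine_model = cytokineModel(),
                        coupling = couplingParams(),
                        enable_coupling = TRUE, exposure_in = 0,
                        cytokine_init = NULL, cycle_index = 1L, ...) {
  kin <- cytokine_model@kinetics
  baselines <- setNames(kin$baseline, kin$name)
  tone <- setNames(as.numeric(patient$cytokines[kin$name]) / baselines[kin$name],
                   kin$name)
  if (anyNA(tone)) stop("patient must carry IL6, IL1B, TNFA concentrations")
  init <- if (is.null(cytokine_init)) patient$cytokines[kin$name] else
    cytokine_init[kin$name]
  inflam <- tryCatch(
    runInflammationPhase(init, protocol@inflam_duration, exposure_in,
                         cytokine_model, production_multiplier = tone),
    error = function(e) stop("inflammation phase (cycle ", cycle_index, "): ",
                             conditionMessage(e)))
  mod <- if (enable_coupling)
    modulationFromPhase(inflam, coupling, baselines)
  else list(induced_tf = 0, atiii_scale = 1, tfpi_scale = 1)
  y0 <- applyModulation(patientInitialState(patient, protocol@tf_trigger), mod)
  coag <- tryCatch(
    simulateNetwork(coagulationModelCache(), protocol@coag_duration,
                    y0 = y0, ...),
    error = function(e) stop("coagulation phase (cycle ", cycle_index, "): ",
                             conditionMessage(e)))
  thr <- totalThrombin(coag)
  metrics <- computeTGMetrics(trajectoryTimes(coag), thr)
  tat <- atiiiIIaSeries(coag)
  exposure_raw <- if (protocol@exposure_metric == "ETP")
    metrics@etp / protocol@coag_duration else metrics@peak
  list(cycle_index = cycle_index, cytokine_trajectory = inflam,
       coagulation_trajectory = coag, metrics = metrics,
       atiii_iia_final = tat[length(tat)], modulation = mod,
       exposure_out = protocol@exposure_gain * exposure_raw)
}

#' Run iterated inflammation-coagulation cycles
#'
#' Cytokine state persists from cycle to cycle while coagulation factors
#' are restored to the patient's values between cycles; cycle k's
#' inflammation phase runs under the thrombin exposure generated by cycle
#' k - 1 (cycle 1 starts cold at zero exposure). With thrombin feedback
#' active this yields progressive amplification of thrombin activity; with
#' feedback silenced (emax = 0 or exposure_gain = 0) all cycles are
#' identical.
#'
#' @inheritParams runTwoPhase
#' @return list of per-cycle results (see [runTwoPhase()]).
#' @export
runCycles <- function(patient, protocol = phaseProtocol(n_cycles = 5L),
                      cytokine_model = cytokineModel(),
                      coupling = couplingParams(),
                      enable_coupling = TRUE, ...) {
  out <- vector("list", protocol@n_cycles)
  exposure <- 0
  cyt_state <- NULL
  for (k in seq_len(protocol@n_cycles)) {
    res <- runTwoPhase(patient, protocol, cytokine_model, coupling,
                       enable_coupling = enable_coupling,
                       exposure_in = exposure, cytokine_init = cyt_state,
                       cycle_index = k, ...)
    out[[k]] <- res
    exposure <- res$exposure_out
    cyt_state <- finalState(res$cytokine_trajectory)
  }
  out
}

#' Reference patient at mean plasma and baseline cytokine levels
#'
#' @param cytokine_model a [CytokineModel-class] supplying the baselines.
#' @return a patient list (see [virtualPatient()]).
#' @export
referencePatient <- function(cytokine_model = cytokineModel()) {
  kin <- cytokine_model@kinetics
  virtualPatient(meanPlasmaConcentrations(),
                 setNames(kin$baseline, kin$name),
                 disease = "Normal", sample_index = 0L, seed = NA_integer_)
}

#' Cytokine dose scan
#'
#' Runs one two-phase protocol per cytokine multiplier, scaling IL-6,
#' IL-1beta and TNF-alpha together relative to baseline. IL-1beta's
#' effective multiplier is clamped at 10 (clinical reports cap its
#' elevation around 10-fold); the other cytokines follow the requested
#' multiplier. Deterministic.
#'
#' @param multipliers positive multipliers (default the standard scan
#'   0.5, 1, 2, 5, 10, 50).
#' @param protocol a [PhaseProtocol-class].
#' @param cytokine_model a [CytokineModel-class].
#' @param coupling a [CouplingParams-class].
#' @param base_patient patient whose cytokines are scaled (default the
#'   mean-plasma reference patient).
#' @param il1b_cap clamp for the IL-1beta multiplier (default 10).
#' @param ... solver options.
#' @return data.frame with one row per multiplier: requested and effective
#'   multipliers, TG metrics, final ATIII-IIa (nM) and induced TF (pM).
#' @export
doseScan <- function(multipliers = c(0.5, 1, 2, 5, 10, 50),
                     protocol = phaseProtocol(),
                     cytokine_model = cytokineModel(),
                     coupling = couplingParams(),
                     base_patient = referencePatient(cytokine_model),
                     il1b_cap = 10, ...) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  kin <- cytokine_model@kinetics
  baselines <- setNames(kin$baseline, kin$name)
  rows <- lapply(multipliers, function(m) {
    eff <- c(IL6 = m, IL1B = min(m, il1b_cap), TNFA = m)
    patient <- base_patient
    patient$cytokines <- baselines[names(eff)] * eff
    res <- runTwoPhase(patient, protocol, cytokine_model, coupling, ...)
    cbind(data.frame(multiplier = m, il1b_multiplier = eff[["IL1B"]]),
          tgMetricsAsRecord(res$metrics),
          data.frame(atiii_iia_final_nM = res$atiii_iia_final * 1e9,
                     induced_tf_pM = res$modulation$induced_tf * 1e12))
  })
  do.call(rbind, rows)
}
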