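#' @import methods
#' @importFrom stats setNames approx cor lm.fit qnorm runif rnorm median quantile
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @useDynLib cytocoag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ReactionNetwork: a mass-action reaction network
#'
#' The simulable object at the heart of the package: a registry of chemical
#' species (name, initial concentration in mol/L, role) plus a list of
#' elementary mass-action reactions with at most two reactants each.
#' Conservation groups are named weighted sums of species that the
#' stoichiometry leaves invariant; they are checked symbolically at
#' construction and numerically after simulation.
#'
#' @slot species data.frame with columns \code{name}, \code{initial}
#'   (mol/L, >= 0) and \code{role} (one of \code{coagulation_factor},
#'   \code{complex}, \code{cytokine}, \code{auxiliary}).
#' @slot reactions list of reactions, each a list with \code{reactants}
#'   (character, length 1 or 2), \code{products} (character, possibly
#'   empty or with repeats) and \code{k} (rate constant, 1/s for
#'   unimolecular, 1/(M s) for bimolecular).
#' @slot conservation named list; each element a named numeric vector of
#'   stoichiometric weights over species whose weighted sum is conserved.
#'
#' @seealso [reactionNetwork()], [simulateNetwork()], [buildCoagulationModel()]
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "list",
                 conservation = "list"))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  msgs <- character()
  if (!all(c("name", "initial", "role") %in% names(sp)))
    return("species must have columns name, initial, role")
  if (anyDuplicated(sp$name))
    msgs <- c(msgs, "species names must be unique")
  if (any(sp$initial < 0))
    msgs <- c(msgs, "initial concentrations must be >= 0")
  roles <- c("coagulation_factor", "complex", "cytokine", "auxiliary")
  if (!all(sp$role %in% roles))
    msgs <- c(msgs, paste("species role must be one of:",
                          paste(roles, collapse = ", ")))
  for (i in seq_along(object@reactions)) {
    rx <- object@reactions[[i]]
    if (length(rx$reactants) < 1L || length(rx$reactants) > 2L)
      msgs <- c(msgs, sprintf("reaction %d: molecularity must be 1 or 2", i))
    unknown <- setdiff(c(rx$reactants, rx$products), sp$name)
    if (length(unknown))
      msgs <- c(msgs, sprintf("reaction %d references unknown species: %s",
                              i, paste(unknown, collapse = ", ")))
    if (is.null(rx$k) || rx$k < 0)
      msgs <- c(msgs, sprintf("reaction %d: rate constant must be >= 0", i))
  }
  for (nm in names(object@conservation)) {
    g <- object@conservation[[nm]]
    unknown <- setdiff(names(g), sp$name)
    if (length(unknown))
      msgs <- c(msgs, sprintf("conservation group '%s' references unknown species: %s",
                              nm, paste(unknown, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Trajectory: time-resolved concentrations from one ODE solve
#'
#' @slot times numeric, seconds, strictly increasing.
#' @slot concentrations numeric matrix, one column per species (mol/L),
#'   one row per time point; first row equals the initial state.
#' @export
setClass("Trajectory",
  representation(times = "numeric", concentrations = "matrix"))

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@concentrations))
    return("times and concentration rows must match")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (is.null(colnames(object@concentrations)))
    return("concentrations must have species column names")
  TRUE
})

#' CytokineModel: first-order kinetics for IL-6, IL-1beta and TNF-alpha
#'
#' Each cytokine decays with first-order rate \code{k_deg = ln 2 / half-life}
#' and is produced at the basal rate \code{p_basal = k_deg * baseline} so
#' that, unstimulated, it holds its normal plasma concentration exactly.
#' Thrombin exposure multiplies production through a Hill law
#' \code{m(E) = 1 + emax E^h / (ec50^h + E^h)}.
#'
#' @slot kinetics data.frame with one row per cytokine: \code{name},
#'   \code{half_life} (s), \code{k_deg} (1/s), \code{baseline} (mol/L),
#'   \code{p_basal} (mol/(L s)), \code{emax}, \code{ec50} (mol/L), \code{hill}.
#' @export
setClass("CytokineModel", representation(kinetics = "data.frame"))

setValidity("CytokineModel", function(object) {
  kin <- object@kinetics
  need <- c("name", "half_life", "k_deg", "baseline", "p_basal",
            "emax", "ec50", "hill")
  if (!all(need %in% names(kin)))
    return(paste("kinetics must have columns:", paste(need, collapse = ", ")))
  if (!setequal(kin$name, c("IL6", "IL1B", "TNFA")))
    return("cytokines must be exactly IL6, IL1B, TNFA")
  if (any(kin$half_life <= 0) || any(kin$baseline <= 0))
    return("half-lives and baselines must be positive")
  if (any(abs(kin$k_deg - log(2) / kin$half_life) > 1e-12 * kin$k_deg))
    return("k_deg must equal ln2/half_life")
  if (any(abs(kin$p_basal - kin$k_deg * kin$baseline) >
          1e-12 * pmax(kin$p_basal, .Machine$double.xmin)))
    return("p_basal must equal k_deg * baseline (steady-state constraint)")
  if (any(kin$emax < 0) || any(kin$hill < 1) || any(kin$ec50 <= 0))
    return("feedback parameters must satisfy emax >= 0, hill >= 1, ec50 > 0")
  TRUE
})

#' CouplingParams: cytokine-to-coagulation input-output laws
#'
#' Phenomenological Hill laws linking cytokine excess over baseline to
#' tissue factor induction, and IL-6 / TNF-alpha excess to suppression of
#' antithrombin III and TFPI availability.
#'
#' @slot induction data.frame, one row per cytokine: \code{name},
#'   \code{vmax} (mol/(L s)), \code{ec50} (mol/L excess), \code{hill}.
#' @slot suppression data.frame, rows \code{ATIII} (driven by IL-6) and
#'   \code{TFPI} (driven by TNF-alpha): \code{target}, \code{driver},
#'   \code{smax} in [0,1), \code{ec50} (mol/L excess), \code{hill}.
#' @slot tf_clearance_halflife seconds; first-order decay of induced TF.
#' @export
setClass("CouplingParams",
  representation(induction = "data.frame", suppression = "data.frame",
                 tf_clearance_halflife = "numeric"))

setValidity("CouplingParams", function(object) {
  ind <- object@induction
  sup <- object@suppression
  if (!all(c("name", "vmax", "ec50", "hill") %in% names(ind)))
    return("induction needs columns name, vmax, ec50, hill")
  if (any(ind$vmax < 0) || any(ind$ec50 <= 0) || any(ind$hill < 1))
    return("induction blocks need vmax >= 0, ec50 > 0, hill >= 1")
  if (!all(c("target", "driver", "smax", "ec50", "hill") %in% names(sup)))
    return("suppression needs columns target, driver, smax, ec50, hill")
  if (any(sup$smax < 0) || any(sup$smax >= 1))
    return("smax must lie in [0, 1)")
  if (object@tf_clearance_halflife <= 0)
    return("tf_clearance_halflife must be positive")
  TRUE
})

#' PhaseProtocol: the two-phase inflammation/coagulation protocol
#'
#' @slot inflam_duration seconds of inflammation preconditioning
#'   (presets: 12 h and 24 h).
#' @slot coag_duration seconds of the coagulation module (default 1200).
#' @slot tf_trigger mol/L tissue factor trigger (default 5 pM).
#' @slot n_cycles number of inflammation-coagulation cycles (>= 1).
#' @slot exposure_metric \code{"ETP"} (time-averaged thrombin) or
#'   \code{"peak"}; how a coagulation phase is summarised into the thrombin
#'   exposure fed back to the next inflammation phase.
#' @slot exposure_gain dimensionless rescaling of the exposure metric into
#'   the feedback Hill law's concentration units.
#' @export
setClass("PhaseProtocol",
  representation(inflam_duration = "numeric", coag_duration = "numeric",
                 tf_trigger = "numeric", n_cycles = "integer",
                 exposure_metric = "character", exposure_gain = "numeric"))

setValidity("PhaseProtocol", function(object) {
  if (object@inflam_duration <= 0 || object@coag_duration <= 0)
    return("durations must be positive")
  if (object@tf_trigger < 0) return("tf_trigger must be >= 0")
  if (object@n_cycles < 1L) return("n_cycles must be >= 1")
  if (!object@exposure_metric %in% c("ETP", "peak"))
    return("exposure_metric must be 'ETP' or 'peak'")
  if (object@exposure_gain < 0) return("exposure_gain must be >= 0")
  TRUE
})

#' TGMetrics: thrombin-generation assay summary of one thrombin curve
#'
#' @slot lag_time seconds (NA for an all-zero curve).
#' @slot time_to_peak seconds (NA for an all-zero curve).
#' @slot peak mol/L.
#' @slot etp mol s / L, endogenous thrombin potential (area under the curve
#'   over the simulated horizon).
#' @slot lag_rule the rule used: \code{"relative"} (10 percent of peak) or
#'   \code{"absolute"} (fixed molar threshold).
#' @export
setClass("TGMetrics",
  representation(lag_time = "numeric", time_to_peak = "numeric",
                 peak = "numeric", etp = "numeric", lag_rule = "character"))

setValidity("TGMetrics", function(object) {
  if (!is.na(object@lag_time) && !is.na(object@time_to_peak) &&
      (object@lag_time < 0 || object@lag_time > object@time_to_peak + 1e-9))
    return("need 0 <= lag_time <= time_to_peak")
  if (object@peak < 0 || object@etp < 0)
    return("peak and etp must be >= 0")
  TRUE
})

#' DiseaseSpec: sampling distributions for one disease cohort
#'
#' Encodes one column of the clinical ranges table: for each coagulation
#' factor and cytokine, a distribution descriptor (uniform range, truncated
#' normal, point mass, below-threshold, or log-uniform) resolvable to a
#' bounded non-negative interval in mol/L.
#'
#' @slot disease one of COVID19, SCD, T2DM, HemophiliaA, Normal.
#' @slot parameters data.frame with one row per parameter: \code{parameter},
#'   \code{kind}, \code{mid}, \code{lo}, \code{hi}, \code{sd}, \code{unit},
#'   \code{note}; values in the units printed in the source table.
#' @export
setClass("DiseaseSpec",
  representation(disease = "character", parameters = "data.frame"))

setValidity("DiseaseSpec", function(object) {
  if (!object@disease %in% c("COVID19", "SCD", "T2DM", "HemophiliaA", "Normal"))
    return("unknown disease label")
  need <- c("parameter", "kind", "mid", "lo", "hi", "sd", "unit")
  if (!all(need %in% names(object@parameters)))
    return(paste("parameters must have columns:", paste(need, collapse = ", ")))
  kinds <- c("range", "mean_sd", "point", "below_frac_ref", "log_range")
  if (!all(object@parameters$kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  TRUE
})

#' SensitivityResult: LHS-PRCC global sensitivity analysis output
#'
#' @slot prcc numeric matrix, parameters (rows, incl. \code{dummy}) by
#'   TG metrics (columns); entries in [-1, 1] or NA for degenerate columns.
#' @slot n_samples number of LHS samples simulated.
#' @slot n_failed number of dropped (failed) simulations.
#' @slot seed the RNG seed used.
#' @slot disease the cohort spec sampled.
#' @export
setClass("SensitivityResult",
  representation(prcc = "matrix", n_samples = "integer", n_failed = "integer",
                 seed = "integer", disease = "character"))

setValidity("SensitivityResult", function(object) {
  v <- object@prcc[!is.na(object@prcc)]
  if (length(v) && any(abs(v) > 1 + 1e-12))
    return("PRCC values must lie in [-1, 1]")
  if (!"dummy" %in% rownames(object@prcc))
    return("a dummy control parameter must be present")
  TRUE
})
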