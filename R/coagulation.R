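# TF-initiated coagulation cascade: the extrinsic (tissue factor) pathway
# of Hockin, Jones, Everse & Mann (2002), 34 species / 42 rate constants,
# with total-TF, prothrombin-derived, antithrombin and TFPI conservation
# groups declared for numerical verification.

.coagFactors <- c("II", "V", "VII", "VIIa", "VIII", "IX", "X", "ATIII", "TFPI")

#' Mean plasma concentrations of the coagulation proteins
#'
#' The reference initial condition of the cascade (mol/L), as used by the
#' Hockin et al. model: all zymogens and inhibitors at their mean plasma
#' levels, VIIa at its trace circulating level, and every activated species
#' or complex at zero.
#'
#' @return named numeric vector over the nine sampled proteins.
#' @export
meanPlasmaConcentrations <- function() {
  c(II = 1.4e-6, V = 2.0e-8, VII = 1.0e-8, VIIa = 1.0e-10, VIII = 7.0e-10,
    IX = 9.0e-8, X = 1.6e-7, ATIII = 3.4e-6, TFPI = 2.5e-9)
}

#' Molecular weights used for mass-to-molar conversion
#'
#' Standard literature values (g/mol); editable because clinical tables
#' print mass concentrations without stating the weights they assume.
#'
#' @return named numeric vector (g/mol) for the coagulation proteins and
#'   cytokines.
#' @export
molecularWeights <- function() {
  c(II = 72000, V = 330000, VII = 50000, VIIa = 50000, VIII = 170000,
    IX = 55000, X = 59000, ATIII = 58000, TFPI = 40000,
    IL6 = 21000, IL1B = 17000, TNFA = 17000)
}

#' Convert a mass concentration to mol/L
#'
#' @param value numeric, >= 0.
#' @param unit one of \code{"mg/L"}, \code{"g/L"}, \code{"ng/mL"},
#'   \code{"pg/mL"} (also accepts \code{ng/ml}, \code{pg/ml}, \code{ug/mL}).
#' @param mw molecular weight in g/mol.
#' @return concentration in mol/L.
#' @examples
#' toMolar(100, "mg/L", 72000)   # prothrombin, 1.39e-6 M
#' toMolar(70, "ng/mL", 40000)   # TFPI, 1.75e-9 M
#' @export
toMolar <- function(value, unit, mw) {
  if (any(value < 0)) stop("mass concentration must be >= 0")
  if (mw <= 0) stop("molecular weight must be positive")
  gl <- switch(tolower(unit),
    "g/l" = 1, "mg/l" = 1e-3, "ug/ml" = 1e-3, "ng/ml" = 1e-6,
    "pg/ml" = 1e-9,
    stop("unknown unit: ", unit))
  value * gl / mw
}

#' Build the TF-initiated coagulation cascade network
#'
#' Reads the packaged rate-constant table (per-constant citations in its
#' note column) and assembles the cascade as a [ReactionNetwork-class].
#' Initial concentrations are all zero; use [coagulationInitialState()] to
#' populate a scenario. Conservation groups are declared for total TF,
#' prothrombin-derived species, total antithrombin and total TFPI.
#'
#' @param rates optional data.frame overriding the packaged rate table
#'   (same columns: \code{reactants}, \code{products}, \code{k} with
#'   \code{|}-separated species lists); every constant is configurable.
#' @return a [ReactionNetwork-class]
#' @export
buildCoagulationModel <- function(rates = NULL) {
  if (is.null(rates)) {
    path <- system.file("extdata", "coagulation_rates.csv",
                        package = "cytocoag", mustWork = TRUE)
    rates <- read.csv(path, stringsAsFactors = FALSE)
  }
  reactions <- lapply(seq_len(nrow(rates)), function(i) {
    reaction(strsplit(rates$reactants[i], "|", fixed = TRUE)[[1]],
             strsplit(rates$products[i], "|", fixed = TRUE)[[1]],
             k = rates$k[i], name = paste0("r", rates$id[i]))
  })
  sp <- unique(unlist(lapply(reactions, function(rx) c(rx$reactants, rx$products))))
  role <- ifelse(sp %in% c(.coagFactors, "TF", "IXa", "Xa", "IIa", "mIIa",
                           "Va", "VIIIa"),
                 "coagulation_factor", "complex")
  species <- data.frame(name = sp, initial = 0, role = role,
                        stringsAsFactors = FALSE)
  conservation <- list(
    tf_total = setNames(rep(1, 8), c("TF", "TF_VII", "TF_VIIa", "TF_VIIa_X",
      "TF_VIIa_Xa", "TF_VIIa_IX", "TF_VIIa_Xa_TFPI", "TF_VIIa_ATIII")),
    prothrombin_total = setNames(rep(1, 6), c("II", "IIa", "mIIa",
      "Xa_Va_II", "IIa_ATIII", "mIIa_ATIII")),
    atiii_total = setNames(rep(1, 6), c("ATIII", "Xa_ATIII", "mIIa_ATIII",
      "IXa_ATIII", "IIa_ATIII", "TF_VIIa_ATIII")),
    tfpi_total = setNames(rep(1, 3), c("TFPI", "Xa_TFPI", "TF_VIIa_Xa_TFPI")))
  reactionNetwork(species, reactions, conservation)
}

#' Perturbation scenario presets
#'
#' Named factor-multiplier maps and TF triggers for the calibration
#' scenarios: the four 25 pM TF inhibitor-knockout runs and the three
#' 5 pM mean-plasma / procoagulant-dominant / anticoagulant-dominant runs
#' (procoagulants II, V, VIII, IX, X at 150 percent with anticoagulants
#' ATIII and TFPI at 50 percent, and the inverse).
#'
#' @param name one of \code{baseline25}, \code{no_atiii}, \code{no_tfpi},
#'   \code{no_atiii_tfpi}, \code{mean_plasma_5pM},
#'   \code{procoagulant_dominant}, \code{anticoagulant_dominant}.
#' @return list with \code{multipliers} (named, over the nine factors) and
#'   \code{tf_trigger} (mol/L).
#' @export
perturbationScenario <- function(name) {
  mult1 <- setNames(rep(1, length(.coagFactors)), .coagFactors)
  pro <- c("II", "V", "VIII", "IX", "X")
  anti <- c("ATIII", "TFPI")
  switch(name,
    baseline25 = list(multipliers = mult1, tf_trigger = 25e-12),
    no_atiii = list(multipliers = replace(mult1, "ATIII", 0),
                    tf_trigger = 25e-12),
    no_tfpi = list(multipliers = replace(mult1, "TFPI", 0),
                   tf_trigger = 25e-12),
    no_atiii_tfpi = list(multipliers = replace(mult1, anti, 0),
                         tf_trigger = 25e-12),
    mean_plasma_5pM = list(multipliers = mult1, tf_trigger = 5e-12),
    procoagulant_dominant = list(
      multipliers = replace(replace(mult1, pro, 1.5), anti, 0.5),
      tf_trigger = 5e-12),
    anticoagulant_dominant = list(
      multipliers = replace(replace(mult1, pro, 0.5), anti, 1.5),
      tf_trigger = 5e-12),
    stop("unknown scenario preset: ", name))
}

#' Initial coagulation state for a perturbation scenario
#'
#' Each zymogen/inhibitor starts at mean plasma concentration times its
#' multiplier, VIIa at its (scaled) trace plasma level, TF at the trigger
#' concentration, and every complex or activated species at zero.
#'
#' @param scenario list with \code{multipliers} (named, dimensionless,
#'   >= 0; missing factors default to 1) and \code{tf_trigger} (mol/L).
#' @param mean_plasma named per-factor mol/L vector
#'   (default [meanPlasmaConcentrations()]).
#' @return named initial state vector over all cascade species.
#' @export
coagulationInitialState <- function(scenario,
                                    mean_plasma = meanPlasmaConcentrations()) {
  mult <- setNames(rep(1, length(.coagFactors)), .coagFactors)
  if (!is.null(scenario$multipliers)) {
    unknown <- setdiff(names(scenario$multipliers), .coagFactors)
    if (length(unknown))
      stop("unknown factor(s) in multiplier map: ",
           paste(unknown, collapse = ", "))
    if (any(scenario$multipliers < 0))
      stop("factor multipliers must be >= 0")
    mult[names(scenario$multipliers)] <- scenario$multipliers
  }
  if (is.null(scenario$tf_trigger) || scenario$tf_trigger < 0)
    stop("scenario must carry a tf_trigger >= 0")
  model <- coagulationModelCache()
  y <- initialState(model)
  y[.coagFactors] <- mean_plasma[.coagFactors] * mult[.coagFactors]
  y["TF"] <- scenario$tf_trigger
  y
}

# The cascade topology is fixed; build it once per session.
.cytocoagCache <- new.env(parent = emptyenv())
coagulationModelCache <- function() {
  if (is.null(.cytocoagCache$model))
    .cytocoagCache$model <- buildCoagulationModel()
  .cytocoagCache$model
}

#' Run a coagulation scenario
#'
#' Convenience wrapper: build the cascade, set the scenario's initial
#' state, and integrate for \code{t_span} seconds at a 1 s reporting step.
#'
#' @param scenario a preset name (see [perturbationScenario()]) or a
#'   scenario list.
#' @param t_span horizon in seconds (default 1200, the standard length of
#'   the coagulation module).
#' @param mean_plasma per-factor mol/L reference.
#' @param ... further solver arguments for [simulateNetwork()].
#' @return a [Trajectory-class]
#' @export
runCoagulation <- function(scenario, t_span = 1200,
                           mean_plasma = meanPlasmaConcentrations(), ...) {
  if (is.character(scenario)) scenario <- perturbationScenario(scenario)
  model <- coagulationModelCache()
  y0 <- coagulationInitialState(scenario, mean_plasma)
  simulateNetwork(model, t_span, y0 = y0, ...)
}

#' Total thrombin series of a coagulation trajectory
#'
#' Total catalytically active thrombin, \code{IIa + w * mIIa}; the default
#' weight 1.2 is the Hockin-lineage convention for meizothrombin activity
#' and is configurable.
#'
#' @param trajectory a [Trajectory-class] containing \code{IIa} and
#'   \code{mIIa}.
#' @param w meizothrombin activity weight.
#' @return numeric vector (mol/L), one value per time point.
#' @export
totalThrombin <- function(trajectory, w = 1.2) {
  need <- c("IIa", "mIIa")
  missing_sp <- setdiff(need, colnames(trajectory@concentrations))
  if (length(missing_sp))
    stop("trajectory lacks species: ", paste(missing_sp, collapse = ", "))
  as.numeric(trajectory@concentrations[, "IIa"] +
             w * trajectory@concentrations[, "mIIa"])
}

#' Thrombin-antithrombin (ATIII-IIa) complex series
#'
#' The cumulative TAT complex, a nondecreasing readout of net thrombin
#' generation (complex formation is irreversible in the cascade).
#'
#' @param trajectory a [Trajectory-class] containing \code{IIa_ATIII}.
#' @return numeric vector (mol/L).
#' @export
atiiiIIaSeries <- function(trajectory) {
  if (!"IIa_ATIII" %in% colnames(trajectory@concentrations))
    stop("trajectory lacks the IIa_ATIII species")
  as.numeric(trajectory@concentrations[, "IIa_ATIII"])
}
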