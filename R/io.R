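# Scenario configuration, fixtures, run manifests and the command-line
# dispatcher behind exec/cytocoag.

.defaultConfig <- function() {
  list(
    seed = 1L,
    protocol = list(inflam_duration = 43200, coag_duration = 1200,
                    tf_trigger = 5e-12, n_cycles = 1L,
                    exposure_metric = "ETP", exposure_gain = 1),
    cytokines = list(
      half_lives = list(IL6 = 3600, IL1B = 3600, TNFA = 276),
      baselines_pg_ml = list(IL6 = 2, IL1B = 0.2, TNFA = 2),
      feedback = list(emax = list(IL6 = 4, IL1B = 0, TNFA = 4),
                      ec50 = list(IL6 = 1e-7, IL1B = 1e-7, TNFA = 1e-7),
                      hill = list(IL6 = 2, IL1B = 2, TNFA = 2))),
    coupling = list(
      vmax = list(IL6 = 3e-16, IL1B = 2e-17, TNFA = 4e-17),
      ec50_fold = list(IL6 = 100, IL1B = 20, TNFA = 20),
      hill = list(IL6 = 2, IL1B = 2, TNFA = 1),
      smax = list(ATIII = 0.5, TFPI = 0.2),
      sup_ec50_fold = list(ATIII = 100, TFPI = 20),
      sup_hill = list(ATIII = 2, TFPI = 2),
      tf_clearance_halflife = 21600),
    cohort = list(disease = "Normal", n = 2000, inflamed = FALSE),
    scenario = "mean_plasma_5pM",
    multipliers = c(0.5, 1, 2, 5, 10, 50),
    output_dir = ".")
}

# Recursively collect keys of `cfg` absent from the default template.
.unknownKeys <- function(cfg, template, prefix = "") {
  bad <- character()
  for (nm in names(cfg)) {
    path <- paste0(prefix, nm)
    if (!nm %in% names(template)) { bad <- c(bad, path); next }
    if (is.list(cfg[[nm]]) && is.list(template[[nm]]) &&
        !is.null(names(template[[nm]])))
      bad <- c(bad, .unknownKeys(cfg[[nm]], template[[nm]],
                                 paste0(path, ".")))
  }
  bad
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (listing every
#' failing key), validates the quantitative constraints and merges the
#' result over the package defaults.
#'
#' @param path file path (extension .yaml/.yml or .json).
#' @return the fully default-resolved configuration list.
#' @export
loadScenarioConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  template <- .defaultConfig()
  bad <- .unknownKeys(cfg, template)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  merged <- modifyList(template, cfg)
  errs <- character()
  pr <- merged$protocol
  for (key in c("inflam_duration", "coag_duration"))
    if (pr[[key]] <= 0) errs <- c(errs, paste0("protocol.", key,
                                               " must be positive"))
  if (pr$tf_trigger < 0) errs <- c(errs, "protocol.tf_trigger must be >= 0")
  if (pr$n_cycles < 1) errs <- c(errs, "protocol.n_cycles must be >= 1")
  if (!pr$exposure_metric %in% c("ETP", "peak"))
    errs <- c(errs, "protocol.exposure_metric must be 'ETP' or 'peak'")
  if (any(unlist(merged$cytokines$half_lives) <= 0))
    errs <- c(errs, "cytokines.half_lives must be positive")
  if (any(unlist(merged$multipliers) <= 0))
    errs <- c(errs, "multipliers must be positive")
  if (merged$cohort$n < 1) errs <- c(errs, "cohort.n must be >= 1")
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  merged
}

#' Save a scenario configuration
#'
#' @param config configuration list.
#' @param path destination (.yaml or .json decides the format).
#' @export
saveScenarioConfig <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

# Build model objects from a validated configuration.
.modelsFromConfig <- function(cfg) {
  mw <- molecularWeights()
  bl <- c(IL6 = unname(toMolar(cfg$cytokines$baselines_pg_ml$IL6, "pg/mL",
                               mw["IL6"])),
          IL1B = unname(toMolar(cfg$cytokines$baselines_pg_ml$IL1B, "pg/mL",
                                mw["IL1B"])),
          TNFA = unname(toMolar(cfg$cytokines$baselines_pg_ml$TNFA, "pg/mL",
                                mw["TNFA"])))
  fb <- cfg$cytokines$feedback
  cyt <- cytokineModel(half_lives = unlist(cfg$cytokines$half_lives),
                       baselines = bl, emax = unlist(fb$emax),
                       ec50 = unlist(fb$ec50), hill = unlist(fb$hill))
  cp <- cfg$coupling
  coup <- couplingParams(baselines = bl, vmax = unlist(cp$vmax),
                         ec50_fold = unlist(cp$ec50_fold),
                         hill = unlist(cp$hill), smax = unlist(cp$smax),
                         sup_ec50_fold = unlist(cp$sup_ec50_fold),
                         sup_hill = unlist(cp$sup_hill),
                         tf_clearance_halflife = cp$tf_clearance_halflife)
  pr <- cfg$protocol
  proto <- phaseProtocol(pr$inflam_duration, pr$coag_duration, pr$tf_trigger,
                         pr$n_cycles, pr$exposure_metric, pr$exposure_gain)
  list(cytokine_model = cyt, coupling = coup, protocol = proto,
       baselines = bl)
}

#' Generate a deterministic test fixture
#'
#' Synthetic inputs with closed-form properties: analytic thrombin curves
#' for the TG metrics, toy reaction networks with exact solutions for the
#' ODE engine, and monotone input-output tables for PRCC checks.
#' Regenerable bit-identically from (name, params, seed).
#'
#' @param name one of \code{triangle_curve}, \code{logistic_atiii_iia},
#'   \code{toy_network}, \code{monotone_sa_dataset}.
#' @param params named list of generator parameters (each generator
#'   documents its own defaults below).
#' @param seed integer seed (only \code{monotone_sa_dataset} consumes
#'   randomness).
#' @return generator-specific object:
#' \describe{
#'   \item{triangle_curve}{list(times, thrombin, peak, ttp, etp): linear
#'     rise to \code{peak} at \code{tpk}, linear fall to zero at
#'     \code{horizon}; exact ETP = peak * horizon / 2.}
#'   \item{logistic_atiii_iia}{list(times, series, midpoint): saturating
#'     logistic accumulation centred at \code{midpoint}.}
#'   \item{toy_network}{a [ReactionNetwork-class]: \code{"decay"} (A -> B,
#'     exact exponential) or \code{"bimolecular"} (A + B -> C plus
#'     C -> A, a stiff-free 3-species loop).}
#'   \item{monotone_sa_dataset}{list(X, y): y = x1 monotone in the first
#'     input, independent uniform noise columns otherwise.}
#' }
#' @export
makeFixture <- function(name, params = list(), seed = 1L) {
  switch(name,
    triangle_curve = {
      p <- modifyList(list(peak = 100e-9, tpk = 600, horizon = 1200,
                           dt = 1), params)
      times <- seq(0, p$horizon, by = p$dt)
      up <- times <= p$tpk
      thr <- ifelse(up, times / p$tpk,
                    pmax(0, (p$horizon - times) / (p$horizon - p$tpk))) *
        p$peak
      list(times = times, thrombin = thr, peak = p$peak, ttp = p$tpk,
           etp = p$peak * p$horizon / 2)
    },
    logistic_atiii_iia = {
      p <- modifyList(list(final = 400e-9, midpoint = 800, slope = 60,
                           horizon = 1200, dt = 1), params)
      times <- seq(0, p$horizon, by = p$dt)
      list(times = times,
           series = p$final / (1 + exp(-(times - p$midpoint) / p$slope)),
           midpoint = p$midpoint)
    },
    toy_network = {
      p <- modifyList(list(kind = "decay", k = 0.1), params)
      if (p$kind == "decay") {
        reactionNetwork(data.frame(name = c("A", "B"), initial = c(1e-6, 0)),
                        list(reaction("A", "B", k = p$k)),
                        conservation = list(total = c(A = 1, B = 1)))
      } else if (p$kind == "bimolecular") {
        reactionNetwork(
          data.frame(name = c("A", "B", "C"), initial = c(1e-6, 8e-7, 0)),
          list(reaction(c("A", "B"), "C", k = 1e6),
               reaction("C", "A", k = 0.05)),
          conservation = list(a_total = c(A = 1, C = 1)))
      } else stop("unknown toy network kind: ", p$kind)
    },
    monotone_sa_dataset = {
      p <- modifyList(list(n = 500, k = 3), params)
      withr_seed(seed, {
        X <- matrix(runif(p$n * p$k), nrow = p$n,
                    dimnames = list(NULL, paste0("x", seq_len(p$k))))
        list(X = X, y = X[, 1])
      })
    },
    stop("unknown fixture generator: ", name))
}

#' Write a run manifest
#'
#' Every CLI subcommand records the configuration digest, seed and package
#' version alongside its outputs.
#'
#' @param config the resolved configuration list.
#' @param path destination JSON path.
#' @param extra optional named list merged into the manifest.
#' @export
writeRunManifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "cytocoag",
    version = as.character(packageVersion("cytocoag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_sha = .configDigest(config)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Small order-stable digest of the serialized configuration (no external
# digest dependency).
.configDigest <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h1 <- 0; h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 33 + b) %% 2147483647
  }
  sprintf("%08x%08x", h1, h2)
}
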