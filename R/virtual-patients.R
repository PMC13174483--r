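# Virtual patient cohorts: disease-specific clinical ranges, unit
# conversion to mol/L, Latin hypercube sampling, and TG-window calibration
# by narrowing the most sensitive factor ranges.

.cytokineNames <- c("IL6", "IL1B", "TNFA")

#' Load a disease sampling specification
#'
#' Reads the packaged clinical-ranges table (one row per disease and
#' parameter, values in the units printed in its source, resolution notes
#' in the \code{note} column) and returns the requested disease column.
#'
#' @param disease one of \code{COVID19}, \code{SCD}, \code{T2DM},
#'   \code{HemophiliaA}, \code{Normal}.
#' @param table optional data.frame overriding the packaged table.
#' @return a [DiseaseSpec-class]
#' @export
diseaseSpec <- function(disease, table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "disease_ranges.csv",
                        package = "cytocoag", mustWork = TRUE)
    table <- read.csv(path, stringsAsFactors = FALSE)
  }
  rows <- table[table$disease == disease, , drop = FALSE]
  if (!nrow(rows)) stop("no rows for disease: ", disease)
  rownames(rows) <- NULL
  new("DiseaseSpec", disease = disease,
      parameters = rows[, setdiff(names(rows), "disease")])
}

setMethod("show", "DiseaseSpec", function(object) {
  cat(sprintf("DiseaseSpec '%s': %d parameters\n", object@disease,
              nrow(object@parameters)))
  print(object@parameters[, c("parameter", "kind", "mid", "lo", "hi", "sd",
                              "unit")], row.names = FALSE)
})

#' Resolve a disease spec into molar sampling distributions
#'
#' Applies the resolution rules: percent-of-normal cells (unit
#' \code{pct_ref}, the convention of clinical factor assays) resolve
#' against the mean-plasma reference concentration, so the Normal column
#' midpoints reproduce the mean-plasma coagulation state exactly;
#' absolute mass concentrations are converted with the configured
#' molecular weights; mean +/- SD cells become normals truncated to
#' mean +/- 3 SD and clipped at zero; "< x%" cells become uniform on
#' (0, x% of reference]; multi-decade ranges are sampled log-uniformly;
#' missing cytokine rows are point masses at the configured normal
#' baselines. All bounds end up in mol/L.
#'
#' @param spec a [DiseaseSpec-class].
#' @param mw named molecular weights, g/mol (default [molecularWeights()]).
#' @param baselines named cytokine baselines, mol/L.
#' @param reference named mol/L mean-plasma reference for \code{pct_ref}
#'   rows (default [meanPlasmaConcentrations()]).
#' @return named list; per parameter a list with \code{type}
#'   (\code{uniform}, \code{loguniform}, \code{truncnorm}, \code{point})
#'   and its molar parameters (\code{lo}, \code{hi}, and for truncated
#'   normals \code{mean}, \code{sd}).
#' @export
resolveSpec <- function(spec, mw = molecularWeights(),
                        baselines = cytokineBaselines(),
                        reference = meanPlasmaConcentrations()) {
  pars <- spec@parameters
  out <- list()
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    nm <- p$parameter
    if (identical(p$unit, "baseline")) {
      out[[nm]] <- list(type = "point", lo = unname(baselines[nm]),
                        hi = unname(baselines[nm]))
      next
    }
    if (identical(p$unit, "pct_ref")) {
      ref <- reference[nm]
      if (is.na(ref)) stop("no mean-plasma reference for ", nm)
      conv <- function(v) unname(v * ref)
    } else {
      m <- mw[nm]
      if (is.na(m)) stop("no molecular weight configured for ", nm)
      conv <- function(v) unname(toMolar(v, p$unit, m))
    }
    out[[nm]] <- switch(p$kind,
      point = list(type = "point", lo = conv(p$mid), hi = conv(p$mid)),
      range = list(type = "uniform", lo = conv(p$lo), hi = conv(p$hi)),
      log_range = {
        if (p$lo <= 0) stop(nm, ": log range needs a positive lower bound")
        list(type = "loguniform", lo = conv(p$lo), hi = conv(p$hi))
      },
      mean_sd = {
        lo <- max(p$mid - 3 * p$sd, 0)
        list(type = "truncnorm", mean = conv(p$mid), sd = conv(p$sd),
             lo = conv(lo), hi = conv(p$mid + 3 * p$sd))
      },
      below_frac_ref = list(type = "uniform", lo = 0, hi = conv(p$mid)),
      stop("unresolvable descriptor kind: ", p$kind))
    if (out[[nm]]$lo < 0 || out[[nm]]$hi < out[[nm]]$lo)
      stop(nm, ": resolved interval is not a bounded nonnegative range")
  }
  out
}

# Quantile transform for one resolved distribution; u in (0,1).
.distQuantile <- function(dist, u) {
  switch(dist$type,
    point = rep(dist$lo, length(u)),
    uniform = dist$lo + u * (dist$hi - dist$lo),
    loguniform = exp(log(dist$lo) + u * (log(dist$hi) - log(dist$lo))),
    truncnorm = {
      plo <- stats::pnorm(dist$lo, dist$mean, dist$sd)
      phi <- stats::pnorm(dist$hi, dist$mean, dist$sd)
      stats::qnorm(plo + u * (phi - plo), dist$mean, dist$sd)
    },
    stop("unknown distribution type: ", dist$type))
}

#' One virtual patient
#'
#' @param factors named mol/L vector over II, V, VII, VIIa, VIII, IX, X,
#'   ATIII, TFPI.
#' @param cytokines named mol/L vector over IL6, IL1B, TNFA.
#' @param disease disease label.
#' @param sample_index integer provenance index within the cohort.
#' @param seed the cohort seed (provenance).
#' @return a patient list.
#' @export
virtualPatient <- function(factors, cytokines, disease = "Normal",
                           sample_index = 1L, seed = NA_integer_) {
  if (any(factors < 0) || any(cytokines < 0))
    stop("patient concentrations must be >= 0")
  list(factors = factors, cytokines = cytokines, disease = disease,
       sample_index = as.integer(sample_index), seed = seed)
}

#' Sample a virtual-patient cohort by Latin hypercube sampling
#'
#' Draws an LHS design over the disease's resolved parameter
#' distributions: for every parameter, exactly one sample falls in each of
#' the n equal-probability strata of its marginal distribution.
#' Reproducible under a fixed seed.
#'
#' @param spec a [DiseaseSpec-class].
#' @param n cohort size (the reference cohort size is 2000; smaller runs
#'   are routine for testing).
#' @param seed integer RNG seed.
#' @param mw,baselines passed to [resolveSpec()].
#' @return data.frame, one row per patient, one column per parameter
#'   (mol/L), with attributes \code{disease} and \code{seed}.
#' @export
sampleCohort <- function(spec, n = 2000, seed = 1L,
                         mw = molecularWeights(),
                         baselines = cytokineBaselines()) {
  stopifnot(n >= 1)
  dists <- resolveSpec(spec, mw, baselines)
  k <- length(dists)
  u <- withr_seed(seed, lhs::randomLHS(n, k))
  cohort <- as.data.frame(lapply(seq_len(k), function(j)
    .distQuantile(dists[[j]], u[, j])))
  names(cohort) <- names(dists)
  attr(cohort, "disease") <- spec@disease
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Extract one patient from a cohort
#'
#' @param cohort data.frame from [sampleCohort()].
#' @param i row index.
#' @return a patient list (see [virtualPatient()]).
#' @export
cohortPatient <- function(cohort, i) {
  row <- unlist(cohort[i, , drop = TRUE])
  fx <- row[setdiff(names(row), .cytokineNames)]
  cyt <- row[.cytokineNames]
  virtualPatient(fx, cyt, disease = attr(cohort, "disease") %||% "Normal",
                 sample_index = i, seed = attr(cohort, "seed") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thrombin-generation metrics for every patient of a cohort
#'
#' For each patient, either the bare coagulation run of the patient's
#' sampled factor concentrations (\code{inflamed = FALSE}) or the full
#' two-phase protocol with the patient's cytokine tone
#' (\code{inflamed = TRUE}).
#'
#' @param cohort data.frame from [sampleCohort()].
#' @param protocol a [PhaseProtocol-class].
#' @param inflamed run the inflammation preconditioning phase?
#' @param cytokine_model,coupling models for the inflamed branch.
#' @param ... solver options.
#' @return data.frame with one row per patient: \code{sample_index},
#'   \code{lag_s}, \code{ttp_s}, \code{peak_nM}, \code{etp_nM_s},
#'   \code{atiii_iia_final_nM}.
#' @export
cohortTG <- function(cohort, protocol = phaseProtocol(), inflamed = FALSE,
                     cytokine_model = cytokineModel(),
                     coupling = couplingParams(), ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    patient <- cohortPatient(cohort, i)
    if (inflamed) {
      res <- runTwoPhase(patient, protocol, cytokine_model, coupling, ...)
      met <- res$metrics
      tat <- res$atiii_iia_final
    } else {
      traj <- simulateNetwork(coagulationModelCache(), protocol@coag_duration,
                              y0 = patientInitialState(patient,
                                                       protocol@tf_trigger),
                              ...)
      met <- computeTGMetrics(trajectoryTimes(traj), totalThrombin(traj))
      tat <- atiiiIIaSeries(traj)[length(trajectoryTimes(traj))]
    }
    cbind(data.frame(sample_index = i), tgMetricsAsRecord(met),
          data.frame(atiii_iia_final_nM = tat * 1e9))
  })
  do.call(rbind, rows)
}

#' Calibrate a cohort spec against TG-metric windows
#'
#' Iteratively narrows the sampling ranges of the most influential
#' coagulation factors (per the supplied sensitivity ranking) until at
#' least \code{target_fraction} of a freshly sampled cohort falls inside
#' every metric window, or \code{max_iter} is reached. At each step the
#' worst-violated metric is identified; for each of the top-ranked
#' factors, the half of its current range that moves the cohort median
#' toward the window (direction = sign of the required shift times the
#' factor's PRCC sign on that metric) is kept (bisection).
#'
#' @param spec a [DiseaseSpec-class].
#' @param windows named list of \code{c(lo, hi)} acceptance intervals in SI
#'   units over any of \code{lag_s}, \code{ttp_s}, \code{peak_nM},
#'   \code{etp_nM_s}.
#' @param sensitivity a [SensitivityResult-class] (or its PRCC matrix) on
#'   the same disease; row names are parameters, columns metrics.
#' @param n_check cohort size per iteration.
#' @param n_top number of factors to narrow (default 3).
#' @param target_fraction required in-window fraction (default 0.6).
#' @param max_iter iteration cap.
#' @param seed RNG seed.
#' @param protocol a [PhaseProtocol-class] (uninflamed TG runs).
#' @return list with the narrowed \code{spec}, the final \code{fraction},
#'   the accepted \code{cohort} and \code{metrics}, \code{iterations}, and
#'   \code{converged}; if the window cannot be reached the result reports
#'   \code{converged = FALSE} together with the per-metric median
#'   diagnostics of the final iteration.
#' @export
calibrateCohort <- function(spec, windows, sensitivity, n_check = 100,
                            n_top = 3, target_fraction = 0.6, max_iter = 8,
                            seed = 1L, protocol = phaseProtocol()) {
  prcc <- if (is(sensitivity, "SensitivityResult")) sensitivity@prcc
          else as.matrix(sensitivity)
  metric_cols <- intersect(names(windows), c("lag_s", "ttp_s", "peak_nM",
                                             "etp_nM_s"))
  if (!length(metric_cols)) stop("windows must name at least one TG metric")
  ranked <- rownames(prcc)[order(-apply(abs(prcc), 1, max, na.rm = TRUE))]
  ranked <- setdiff(ranked, c("dummy", .cytokineNames))
  top <- head(ranked, n_top)
  cur <- spec
  for (it in seq_len(max_iter)) {
    cohort <- sampleCohort(cur, n_check, seed = seed + it)
    mets <- cohortTG(cohort, protocol, inflamed = FALSE)
    inside <- rep(TRUE, nrow(mets))
    deficit <- setNames(numeric(length(metric_cols)), metric_cols)
    for (mc in metric_cols) {
      w <- windows[[mc]]
      inside <- inside & mets[[mc]] >= w[1] & mets[[mc]] <= w[2]
      med <- stats::median(mets[[mc]])
      deficit[mc] <- if (med < w[1]) (w[1] - med) / max(abs(w[1]), 1e-12)
        else if (med > w[2]) (med - w[2]) / max(abs(w[2]), 1e-12) else 0
    }
    fraction <- mean(inside)
    if (fraction >= target_fraction)
      return(list(spec = cur, fraction = fraction,
                  cohort = cohort[inside, , drop = FALSE],
                  metrics = mets, iterations = it, converged = TRUE))
    worst <- names(deficit)[which.max(deficit)]
    if (deficit[worst] == 0) {
      # medians inside every window yet too few patients qualify: shrink
      # the top factors symmetrically to tighten the spread
      for (f in top) cur <- .narrowParameter(cur, f, direction = 0)
      next
    }
    w <- windows[[worst]]
    med <- stats::median(mets[[worst]])
    needed <- if (med < w[1]) +1 else -1
    for (f in top) {
      s <- sign(prcc[f, worst])
      if (is.na(s) || s == 0) next
      cur <- .narrowParameter(cur, f, direction = needed * s)
    }
  }
  list(spec = cur, fraction = fraction, cohort = cohort[inside, , drop = FALSE],
       metrics = mets, iterations = max_iter, converged = FALSE,
       diagnostics = deficit)
}

# Halve a parameter's sampling range: direction +1 keeps the upper half,
# -1 the lower half, 0 shrinks symmetrically about the midpoint.
.narrowParameter <- function(spec, parameter, direction) {
  pars <- spec@parameters
  i <- which(pars$parameter == parameter)
  if (!length(i)) return(spec)
  p <- pars[i, ]
  if (p$kind %in% c("range", "log_range")) {
    mid <- (p$lo + p$hi) / 2
    if (direction > 0) pars$lo[i] <- mid
    else if (direction < 0) pars$hi[i] <- mid
    else { pars$lo[i] <- (p$lo + mid) / 2; pars$hi[i] <- (p$hi + mid) / 2 }
  } else if (p$kind == "mean_sd") {
    shift <- direction * p$sd / 2
    pars$mid[i] <- max(p$mid + shift, 0)
    pars$sd[i] <- p$sd / 2
  } else if (p$kind == "below_frac_ref") {
    if (direction < 0) pars$mid[i] <- p$mid / 2  # tightens the (0, 1%] cap
  }
  new("DiseaseSpec", disease = spec@disease, parameters = pars)
}
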