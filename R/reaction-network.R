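#' Construct a mass-action reaction network
#'
#' @param species data.frame with columns \code{name}, \code{initial}
#'   (mol/L) and optionally \code{role} (defaults to \code{auxiliary}).
#' @param reactions list of reactions; each created with [reaction()].
#' @param conservation named list of named numeric weight vectors; each
#'   weighted sum over species must be left invariant by every reaction
#'   (checked symbolically, see [checkConservationSymbolic()]).
#' @return A [ReactionNetwork-class] object.
#' @examples
#' net <- reactionNetwork(
#'   data.frame(name = c("A", "B"), initial = c(1e-6, 0)),
#'   list(reaction("A", "B", k = 0.1)),
#'   conservation = list(total = c(A = 1, B = 1)))
#' @export
reactionNetwork <- function(species, reactions, conservation = list()) {
  if (is.null(species$role)) species$role <- "auxiliary"
  species$name <- as.character(species$name)
  obj <- new("ReactionNetwork", species = species, reactions = reactions,
             conservation = conservation)
  bad <- checkConservationSymbolic(obj)
  if (length(bad))
    stop("conservation group(s) not invariant under the stoichiometry: ",
         paste(bad, collapse = ", "))
  obj
}

#' Define one mass-action reaction
#'
#' @param reactants character vector of 1 or 2 species names (repeat a name
#'   for a homodimerisation).
#' @param products character vector of product species names (may be empty
#'   for pure degradation, and may contain repeats).
#' @param k rate constant: 1/s for unimolecular, 1/(M s) for bimolecular.
#' @param name optional label.
#' @export
reaction <- function(reactants, products = character(), k, name = NULL) {
  list(reactants = as.character(reactants),
       products = as.character(products), k = as.numeric(k), name = name)
}

#' @describeIn speciesNames species names of a network
#' @param x object to query
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @describeIn initialState named initial concentration vector of a network
#' @param ... unused
#' @export
setMethod("initialState", "ReactionNetwork", function(x, ...)
  setNames(x@species$initial, x@species$name))

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions, %d conservation group(s)\n",
              nrow(object@species), length(object@reactions),
              length(object@conservation)))
  roles <- table(object@species$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
})

# Net stoichiometry matrix (species x reactions).
stoichiometryMatrix <- function(model) {
  sp <- model@species$name
  S <- matrix(0, nrow = length(sp), ncol = length(model@reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(model@reactions)) {
    rx <- model@reactions[[j]]
    for (r in rx$reactants) S[r, j] <- S[r, j] - 1
    for (p in rx$products)  S[p, j] <- S[p, j] + 1
  }
  S
}

#' Check conservation groups symbolically against the stoichiometry
#'
#' A weighted sum \eqn{w^T y} is invariant iff \eqn{w^T S = 0} where S is
#' the net stoichiometry matrix.
#'
#' @param model a [ReactionNetwork-class]
#' @return character vector of group names that are NOT invariant (empty if
#'   all hold).
#' @export
checkConservationSymbolic <- function(model) {
  if (!length(model@conservation)) return(character())
  S <- stoichiometryMatrix(model)
  bad <- character()
  for (nm in names(model@conservation)) {
    g <- model@conservation[[nm]]
    w <- setNames(numeric(nrow(S)), rownames(S))
    w[names(g)] <- g
    if (any(abs(as.numeric(w %*% S)) > 1e-12)) bad <- c(bad, nm)
  }
  bad
}

#' Build a mass-action derivative evaluator
#'
#' Compiles the network into index arrays and returns a deterministic,
#' side-effect-free evaluator mapping (state vector, time) to d(state)/dt.
#' The hot loop runs in C.
#'
#' @param model a [ReactionNetwork-class]
#' @return function \code{f(t, y)} returning the named derivative vector.
#' @examples
#' net <- reactionNetwork(data.frame(name = c("A", "B"), initial = c(1, 0)),
#'                        list(reaction("A", "B", k = 0.1)))
#' f <- buildRhs(net)
#' f(0, c(A = 1, B = 0))  # dA/dt = -0.1, dB/dt = +0.1
#' @export
buildRhs <- function(model) {
  sp <- model@species$name
  idx <- setNames(seq_along(sp), sp)
  nr <- length(model@reactions)
  r1 <- integer(nr); r2 <- integer(nr); kk <- numeric(nr)
  for (j in seq_len(nr)) {
    rx <- model@reactions[[j]]
    ri <- idx[rx$reactants]
    if (anyNA(ri)) stop("unknown species in reaction ", j)
    r1[j] <- ri[1] - 1L
    r2[j] <- if (length(ri) == 2L) ri[2] - 1L else -1L
    kk[j] <- rx$k
  }
  S <- stoichiometryMatrix(model)
  nz <- which(S != 0, arr.ind = TRUE)
  si <- as.integer(nz[, 1] - 1L); sj <- as.integer(nz[, 2] - 1L)
  sv <- S[nz]
  force(sp)
  function(t, y) {
    dy <- massActionDeriv(as.numeric(y), kk, r1, r2, si, sj, sv)
    names(dy) <- sp
    dy
  }
}

#' Integrate a reaction network with a stiff ODE solver
#'
#' Solves the mass-action ODE system with \pkg{deSolve}'s \code{lsoda}
#' (switching to BDF in stiff regions). Coagulation cascades span pM to
#' micromolar concentrations and are stiff, hence the tight default
#' tolerances.
#'
#' @param model a [ReactionNetwork-class]
#' @param t_span final time in seconds (> 0; \code{t_span = 0} returns the
#'   initial state only).
#' @param dt reporting step in seconds (default 1 s).
#' @param y0 optional named initial state overriding the model's.
#' @param rtol,atol relative/absolute solver tolerances (mol/L for atol).
#' @param maxsteps maximum internal solver steps.
#' @param ... passed to [simulateNetwork()] methods.
#' @return A [Trajectory-class].
#' @export
setMethod("simulateNetwork", "ReactionNetwork",
  function(model, t_span, dt = 1, y0 = NULL, rtol = 1e-8, atol = 1e-12,
           maxsteps = 50000, ...) {
    if (t_span < 0) stop("t_span must be >= 0")
    y <- initialState(model)
    if (!is.null(y0)) {
      unknown <- setdiff(names(y0), names(y))
      if (length(unknown)) stop("unknown species in y0: ",
                                paste(unknown, collapse = ", "))
      y[names(y0)] <- y0
    }
    if (t_span == 0)
      return(new("Trajectory", times = 0,
                 concentrations = matrix(y, nrow = 1,
                                         dimnames = list(NULL, names(y)))))
    f <- buildRhs(model)
    times <- seq(0, t_span, by = dt)
    if (times[length(times)] < t_span) times <- c(times, t_span)
    out <- deSolve::ode(y = y, times = times,
                        func = function(t, y, p) list(f(t, y)),
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
    diagn <- attr(out, "istate")
    if (!is.null(diagn) && diagn[1] < 0)
      stop(sprintf("ODE solver failed near t = %.6g s (istate = %d)",
                   out[nrow(out), 1], diagn[1]))
    if (nrow(out) < length(times))
      stop(sprintf("ODE solver stopped early near t = %.6g s",
                   out[nrow(out), 1]))
    conc <- out[, -1, drop = FALSE]
    new("Trajectory", times = as.numeric(out[, 1]),
        concentrations = matrix(conc, nrow = nrow(out),
                                dimnames = list(NULL, colnames(conc))))
  })

#' @describeIn trajectoryTimes time grid of a trajectory (seconds)
#' @export
setMethod("trajectoryTimes", "Trajectory", function(x) x@times)

#' @describeIn concentrations concentration series of a trajectory
#' @param species optional species names to extract; with one name a
#'   numeric vector is returned, otherwise a matrix.
#' @export
setMethod("concentrations", "Trajectory", function(x, species) {
  if (missing(species)) return(x@concentrations)
  missing_sp <- setdiff(species, colnames(x@concentrations))
  if (length(missing_sp))
    stop("species not in trajectory: ", paste(missing_sp, collapse = ", "))
  x@concentrations[, species, drop = length(species) == 1]
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] s, %d species\n",
              length(object@times), object@times[1],
              object@times[length(object@times)],
              ncol(object@concentrations)))
})

#' Final state of a trajectory
#' @param x a [Trajectory-class]
#' @return named numeric vector of concentrations at the last time point.
#' @export
finalState <- function(x) {
  stopifnot(is(x, "Trajectory"))
  setNames(x@concentrations[nrow(x@concentrations), ],
           colnames(x@concentrations))
}

#' Numerically check conservation groups along a trajectory
#'
#' @param trajectory a [Trajectory-class] produced from \code{model}
#' @param model the [ReactionNetwork-class] declaring the groups
#' @return named numeric vector: per group, the maximum relative drift
#'   \eqn{max_t |w^T y(t) - w^T y(0)| / w^T y(0)}.
#' @export
checkConservation <- function(trajectory, model) {
  groups <- model@conservation
  if (!length(groups)) return(setNames(numeric(0), character(0)))
  out <- setNames(numeric(length(groups)), names(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    missing_sp <- setdiff(names(g), colnames(trajectory@concentrations))
    if (length(missing_sp))
      stop("conservation group '", nm, "' references species absent from the ",
           "trajectory: ", paste(missing_sp, collapse = ", "))
    tot <- as.numeric(trajectory@concentrations[, names(g), drop = FALSE] %*% g)
    if (abs(tot[1]) < .Machine$double.xmin) {
      out[nm] <- if (max(abs(tot)) == 0) 0 else Inf
    } else {
      out[nm] <- max(abs(tot - tot[1])) / abs(tot[1])
    }
  }
  out
}

#' Serialize a network to JSON / read it back
#'
#' The schema holds species (name, initial, role), reactions (reactants,
#' products, rate constant, optional name) and conservation groups; a
#' round trip reproduces the network exactly.
#'
#' @param model a [ReactionNetwork-class]
#' @param path file path; for [networkToJSON()] the destination, for
#'   [networkFromJSON()] the source.
#' @export
networkToJSON <- function(model, path) {
  obj <- list(
    species = model@species,
    reactions = lapply(model@reactions, function(rx)
      list(reactants = rx$reactants, products = rx$products, k = rx$k,
           name = rx$name)),
    conservation = lapply(model@conservation, function(g)
      list(species = names(g), weight = unname(g))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname networkToJSON
#' @export
networkFromJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  reactions <- lapply(seq_len(nrow(obj$reactions)), function(i) {
    rx <- obj$reactions[i, ]
    nm <- unlist(rx$name)
    reaction(unlist(rx$reactants), unlist(rx$products), k = rx$k,
             name = if (length(nm) == 1 && !is.na(nm)) nm else NULL)
  })
  conservation <- lapply(obj$conservation, function(g)
    setNames(g$weight, g$species))
  reactionNetwork(obj$species, reactions, conservation)
}

#' Write a trajectory to CSV
#'
#' Header row is \code{time_s,<species...>}; concentrations in mol/L.
#'
#' @param trajectory a [Trajectory-class]
#' @param path destination file
#' @export
trajectoryToCSV <- function(trajectory, path) {
  df <- data.frame(time_s = trajectory@times,
                   trajectory@concentrations, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
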