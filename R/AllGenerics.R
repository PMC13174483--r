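#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname initialState
#' @export
setGeneric("initialState", function(x, ...) standardGeneric("initialState"))

#' @rdname trajectoryTimes
#' @export
setGeneric("trajectoryTimes", function(x) standardGeneric("trajectoryTimes"))

#' @rdname concentrations
#' @export
setGeneric("concentrations", function(x, species) standardGeneric("concentrations"))

#' @rdname simulateNetwork
#' @export
setGeneric("simulateNetwork",
  function(model, t_span, ...) standardGeneric("simulateNetwork"))
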