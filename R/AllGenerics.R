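#' @rdname timepoints
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' @rdname snapshot
#' @export
setGeneric("snapshot", function(x, timepoint, compartment = NULL)
  standardGeneric("snapshot"))

#' @rdname isNormalized
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname coupling
#' @export
setGeneric("coupling", function(x) standardGeneric("coupling"))

#' @rdname transitionMatrix
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname sourceMarginal
#' @export
setGeneric("sourceMarginal", function(x) standardGeneric("sourceMarginal"))

#' @rdname growthFactors
#' @export
setGeneric("growthFactors", function(x) standardGeneric("growthFactors"))
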