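#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname accessors
#' @export
setGeneric("likelihood", function(x) standardGeneric("likelihood"))

#' @rdname accessors
#' @export
setGeneric("transitions", function(x, action) standardGeneric("transitions"))

#' @rdname accessors
#' @export
setGeneric("initialDist", function(x) standardGeneric("initialDist"))

#' @rdname accessors
#' @export
setGeneric("actions", function(x) standardGeneric("actions"))

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("beliefProbs", function(x) standardGeneric("beliefProbs"))

#' @rdname environmentalPrecision
#' @export
setGeneric("environmentalPrecision",
           function(x, ...) standardGeneric("environmentalPrecision"))

#' @rdname applyGainControl
#' @export
setGeneric("applyGainControl",
           function(x, gamma) standardGeneric("applyGainControl"))
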