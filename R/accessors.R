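#' Accessors for model objects
#'
#' Slot access for [GenerativeModel]/[GenerativeProcess], [BeliefState],
#' [CountMatrix], [PrecisionReport], [SalienceReport] and [BundledConfig]
#' objects. Use these rather than \code{@}.
#'
#' @param x the object.
#' @param action for \code{transitions}: an action label or index selecting
#'   one B slice; omit to get the full named list of slices.
#' @name accessors
NULL

setMethod("states", "GenerativeModel", function(x) x@states)
setMethod("observations", "GenerativeModel", function(x) x@observations)
setMethod("likelihood", "GenerativeModel", function(x) x@A)
setMethod("transitions", "GenerativeModel", function(x, action) {
    if (missing(action)) return(x@B)
    if (is.character(action))
        .matchLabel(action, names(x@B), "action")
    x@B[[action]]
})
setMethod("initialDist", "GenerativeModel", function(x) x@D)
setMethod("actions", "GenerativeModel", function(x) names(x@B))
setMethod("modelName", "GenerativeModel", function(x) x@name)

setMethod("counts", "CountMatrix", function(x) x@counts)
setMethod("beliefProbs", "BeliefState", function(x) x@probs)

#' @rdname accessors
#' @export
beliefTime <- function(x) {
    stopifnot(is(x, "BeliefState"))
    x@time
}

#' @rdname accessors
#' @export
columnEntropies <- function(x) {
    stopifnot(is(x, "PrecisionReport"))
    x@columnEntropies
}

#' @rdname accessors
#' @export
totalEntropy <- function(x) {
    stopifnot(is(x, "PrecisionReport"))
    x@totalEntropy
}

#' @rdname accessors
#' @export
maxEntropy <- function(x) {
    stopifnot(is(x, "PrecisionReport"))
    x@maxEntropy
}

#' @rdname accessors
#' @export
normalizedPrecision <- function(x) {
    stopifnot(is(x, "PrecisionReport"))
    x@normalizedPrecision
}

#' @rdname accessors
#' @export
salienceGains <- function(x) {
    stopifnot(is(x, "SalienceReport"))
    x@gains
}

#' @rdname accessors
#' @export
selectedAction <- function(x) {
    stopifnot(is(x, "SalienceReport"))
    x@selected
}

#' @rdname accessors
#' @export
configModel <- function(x) {
    stopifnot(is(x, "BundledConfig"))
    x@model
}

#' @rdname accessors
#' @export
configProcess <- function(x) {
    stopifnot(is(x, "BundledConfig"))
    x@process
}

#' @rdname accessors
#' @export
configName <- function(x) {
    stopifnot(is(x, "BundledConfig"))
    x@name
}
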