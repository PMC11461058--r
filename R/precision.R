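#' Shannon entropy of one categorical column
#'
#' \eqn{H(p) = -\sum_k p_k \log p_k} in nats, with \eqn{0 \log 0 = 0}. For a
#' distribution over \code{K} outcomes the value lies in \code{[0, log K]}:
#' 0 for a deterministic (one-hot) column, \code{log K} at the uniform.
#'
#' @param p a probability vector (must sum to 1 within 1e-9).
#' @param base logarithm base for reporting; the default \code{exp(1)} gives
#'   nats, \code{2} gives bits. Internal computations always use nats.
#' @return single non-negative numeric.
#' @examples
#' columnEntropy(c(1, 0, 0))        # 0: a deterministic mapping
#' columnEntropy(rep(1 / 3, 3))     # log(3), maximal uncertainty
#' @export
columnEntropy <- function(p, base = exp(1)) {
    .assertProb(p, "column")
    .entropy(p) / log(base)
}

#' Environmental precision of a parameter matrix
#'
#' Sums the Shannon entropy of every column of a column-stochastic parameter
#' matrix (likelihood A or one transition slice of B) to obtain the
#' environmental entropy of the whole matrix, and reports alongside it the
#' maximum attainable entropy \code{ncol * log(nrow)} and the normalised
#' environmental precision \code{1 - total/max}. A fully deterministic matrix
#' (all entries 1 or 0) has total entropy 0 and precision 1; an all-uniform
#' matrix has precision 0. High precision of A means shapes reliably afford
#' specific functions; high precision of B means shapes change (or persist)
#' reliably across periods.
#'
#' @param x a column-stochastic matrix, or a [GenerativeModel] /
#'   [GenerativeProcess] together with \code{matrix}/\code{slice} selecting
#'   which parameter to score.
#' @param matrix for model objects: \code{"A"} or \code{"B"}.
#' @param slice for \code{matrix = "B"}: action label or index of the slice.
#' @param ... passed through to the matrix method.
#' @return a [PrecisionReport].
#' @examples
#' kd <- configModel(loadBundled("knapping_tool_deterministic"))
#' environmentalPrecision(kd, matrix = "A")   # entropy 0, precision 1
#' ku <- configModel(loadBundled("knapping_tool_uniform"))
#' totalEntropy(environmentalPrecision(ku, matrix = "A"))  # 3 * log(3)
#' @name environmentalPrecision
NULL

setMethod("environmentalPrecision", "matrix", function(x, ...) {
    .assertColumnStochastic(x, "parameter matrix")
    h <- apply(x, 2L, .entropy)
    if (is.null(names(h)) && !is.null(colnames(x))) names(h) <- colnames(x)
    total <- sum(h)
    hmax <- ncol(x) * log(nrow(x))
    prec <- if (hmax == 0) 1 else 1 - total / hmax
    new("PrecisionReport", columnEntropies = h, totalEntropy = total,
        maxEntropy = hmax,
        normalizedPrecision = min(max(prec, 0), 1))
})

setMethod("environmentalPrecision", "GenerativeModel",
    function(x, matrix = c("A", "B"), slice = 1L, ...) {
        matrix <- match.arg(matrix)
        M <- if (matrix == "A") x@A else transitions(x, slice)
        environmentalPrecision(M)
    })

#' Covert-attention gain control on a likelihood matrix
#'
#' Raises every column of A to the power \code{gamma} and renormalises —
#' temperature scaling of the likelihood on the log scale. \code{gamma > 1}
#' sharpens the columns (more weight on the dominant observation);
#' \code{gamma < 1} flattens them; \code{gamma = 1} is the identity. At
#' \code{gamma = 0} structural zeros are preserved: zero entries stay zero and
#' the column becomes uniform over its support.
#'
#' @param x a likelihood matrix (column-stochastic) or a [GenerativeModel],
#'   whose A is rescaled in place.
#' @param gamma non-negative gain exponent.
#' @return object of the same class as \code{x} with the rescaled A.
#' @examples
#' applyGainControl(matrix(c(0.9, 0.1), 2, 1), gamma = 2)
#' @name applyGainControl
NULL

setMethod("applyGainControl", "matrix", function(x, gamma) {
    .assertColumnStochastic(x, "likelihood matrix")
    if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
        gamma < 0)
        stop("gamma must be a single non-negative number", call. = FALSE)
    out <- apply(x, 2L, function(col) {
        w <- if (gamma == 0) as.numeric(col > 0) else col^gamma
        w / sum(w)
    })
    out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
    out
})

setMethod("applyGainControl", "GenerativeModel", function(x, gamma) {
    x@A <- applyGainControl(x@A, gamma)
    validObject(x)
    x
})
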