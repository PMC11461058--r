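#' @import methods
NULL

#' Categorical hidden Markov model of an artefact
#'
#' A \code{GenerativeModel} holds the agent's joint model of hidden states and
#' observations: the state space (e.g. hammer shapes \code{"rounded"},
#' \code{"squared"}, \code{"sharp"}), the observation space (the functions the
#' shapes afford, e.g. \code{"crushing"}, \code{"cracking"}, \code{"cutting"}),
#' a likelihood matrix \code{A} (observations by states, column-stochastic),
#' one or more action-conditioned transition slices \code{B} (each states by
#' states, column \code{j} the distribution over the next state given previous
#' state \code{j}), and an initial state distribution \code{D}. Columns, not
#' rows, are the categorical distributions throughout.
#'
#' A \code{GenerativeProcess} has the same structure and represents the
#' environment's true parameters, from which observations are actually
#' generated; the distinction is semantic and enforced by class so that
#' functions can state which side of the agent/environment divide they expect.
#'
#' @slot name single string naming the configuration.
#' @slot states character vector of unique hidden-state labels.
#' @slot observations character vector of unique observation labels.
#' @slot A numeric matrix, \code{length(observations)} rows by
#'   \code{length(states)} columns; every column sums to 1 within 1e-9.
#' @slot B named list of numeric \code{|S| x |S|} matrices, one per action;
#'   every column of every slice sums to 1 within 1e-9.
#' @slot D numeric vector over states, summing to 1 within 1e-9.
#'
#' @seealso [generativeModel()], [generativeProcess()], [forwardFilter()],
#'   [environmentalPrecision()]
#' @aliases GenerativeProcess-class
#' @exportClass GenerativeModel GenerativeProcess
setClass("GenerativeModel",
    representation(
        name = "character",
        states = "character",
        observations = "character",
        A = "matrix",
        B = "list",
        D = "numeric"
    )
)

setClass("GenerativeProcess", contains = "GenerativeModel")

.validGenerativeModel <- function(object) {
    msg <- character()
    collect <- function(expr) {
        tryCatch({ expr; NULL },
                 error = function(e) conditionMessage(e))
    }
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "name must be a single string")
    m <- collect(.assertLabels(object@states, "state labels"))
    if (!is.null(m)) msg <- c(msg, m)
    m <- collect(.assertLabels(object@observations, "observation labels"))
    if (!is.null(m)) msg <- c(msg, m)
    nS <- length(object@states)
    nO <- length(object@observations)
    if (!identical(dim(object@A), c(nO, nS)))
        msg <- c(msg, sprintf("A must be %d x %d (observations x states)",
                              nO, nS))
    else {
        m <- collect(.assertColumnStochastic(object@A, "likelihood matrix A"))
        if (!is.null(m)) msg <- c(msg, m)
    }
    if (length(object@B) < 1L || is.null(names(object@B)) ||
        anyDuplicated(names(object@B)) || any(!nzchar(names(object@B))))
        msg <- c(msg, "B must be a non-empty list of uniquely named slices")
    else for (a in names(object@B)) {
        slice <- object@B[[a]]
        if (!identical(dim(slice), c(nS, nS))) {
            msg <- c(msg, sprintf("B slice '%s' must be %d x %d", a, nS, nS))
        } else {
            m <- collect(.assertColumnStochastic(
                slice, sprintf("transition slice '%s'", a)))
            if (!is.null(m)) msg <- c(msg, m)
        }
    }
    if (length(object@D) != nS)
        msg <- c(msg, "D must have one entry per state")
    else {
        m <- collect(.assertProb(object@D, "initial state distribution D"))
        if (!is.null(m)) msg <- c(msg, m)
    }
    if (length(msg)) msg else TRUE
}

setValidity("GenerativeModel", .validGenerativeModel)

#' Posterior belief over hidden states at one time step
#'
#' @slot probs named numeric vector over states, summing to 1 within 1e-9.
#' @slot time non-negative integer time index (0 = prior to any evidence).
#' @exportClass BeliefState
setClass("BeliefState",
    representation(probs = "numeric", time = "integer")
)

setValidity("BeliefState", function(object) {
    msg <- character()
    m <- tryCatch({ .assertProb(object@probs, "belief"); NULL },
                  error = function(e) conditionMessage(e))
    if (!is.null(m)) msg <- c(msg, m)
    if (is.null(names(object@probs)))
        msg <- c(msg, "belief probabilities must be named by state")
    if (length(object@time) != 1L || is.na(object@time) || object@time < 0L)
        msg <- c(msg, "time must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

#' Non-negative evidence counts shaped like a model parameter
#'
#' Count matrices accumulate (possibly fractional) evidence weights; column
#' normalisation turns them into a likelihood matrix, a transition slice, or
#' (for a one-column matrix) an initial state distribution. Priors are just
#' initial counts.
#'
#' @slot counts non-negative numeric matrix with row and column dimnames.
#' @exportClass CountMatrix
setClass("CountMatrix", representation(counts = "matrix"))

setValidity("CountMatrix", function(object) {
    M <- object@counts
    if (!is.matrix(M) || !is.numeric(M) || anyNA(M))
        return("counts must be a numeric matrix without NAs")
    if (any(M < 0))
        return("counts must be non-negative")
    if (is.null(rownames(M)) || is.null(colnames(M)))
        return("counts must carry row and column labels")
    TRUE
})

#' Environmental precision of a parameter matrix
#'
#' Per-column Shannon entropies (nats) of a column-stochastic matrix, their
#' sum (the environmental entropy of the whole matrix), the maximum attainable
#' entropy \code{ncol * log(nrow)}, and the normalised precision
#' \code{1 - total/max} (1 for a deterministic matrix, 0 for an all-uniform
#' one; defined as 1 when the maximum is 0).
#'
#' @slot columnEntropies named numeric vector, nats per column.
#' @slot totalEntropy,maxEntropy,normalizedPrecision single numerics.
#' @exportClass PrecisionReport
setClass("PrecisionReport",
    representation(
        columnEntropies = "numeric",
        totalEntropy = "numeric",
        maxEntropy = "numeric",
        normalizedPrecision = "numeric"
    )
)

setValidity("PrecisionReport", function(object) {
    msg <- character()
    tol <- 1e-6
    if (abs(object@totalEntropy - sum(object@columnEntropies)) > tol)
        msg <- c(msg, "totalEntropy must equal the sum of columnEntropies")
    if (object@totalEntropy < -tol ||
        object@totalEntropy > object@maxEntropy + tol)
        msg <- c(msg, "totalEntropy must lie in [0, maxEntropy]")
    if (object@normalizedPrecision < -tol ||
        object@normalizedPrecision > 1 + tol)
        msg <- c(msg, "normalizedPrecision must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Expected information gain of candidate actions
#'
#' @slot gains named numeric vector: expected information gain (nats) per
#'   action; non-negative (tiny negative round-off is clamped to 0).
#' @slot selected label of the action attaining the maximum gain (ties broken
#'   by the earliest action in the supplied order).
#' @exportClass SalienceReport
setClass("SalienceReport",
    representation(gains = "numeric", selected = "character")
)

setValidity("SalienceReport", function(object) {
    msg <- character()
    if (is.null(names(object@gains)) || length(object@gains) < 1L)
        msg <- c(msg, "gains must be a non-empty named vector")
    if (any(object@gains < 0))
        msg <- c(msg, "gains must be non-negative")
    if (length(object@selected) != 1L ||
        !(object@selected %in% names(object@gains)))
        msg <- c(msg, "selected must name one of the scored actions")
    else if (object@gains[[object@selected]] < max(object@gains) - 1e-12)
        msg <- c(msg, "selected action must attain the maximum gain")
    if (length(msg)) msg else TRUE
})

#' A bundled model/process configuration
#'
#' Pairs a [GenerativeModel] with the matching [GenerativeProcess] under a
#' registry name; see [loadBundled()] for the available configurations.
#'
#' @slot name registry name of the configuration.
#' @slot model the agent's generative model.
#' @slot process the environment's generative process.
#' @exportClass BundledConfig
setClass("BundledConfig",
    representation(
        name = "character",
        model = "GenerativeModel",
        process = "GenerativeProcess"
    )
)

# ---- constructors -----------------------------------------------------------

.buildModel <- function(class, states, observations, A, B, D, name) {
    .assertLabels(states, "state labels")
    .assertLabels(observations, "observation labels")
    A <- as.matrix(A)
    storage.mode(A) <- "double"
    dimnames(A) <- list(observations, states)
    if (is.matrix(B)) B <- list(advance = B)
    if (is.null(names(B)) && length(B) == 1L) names(B) <- "advance"
    B <- lapply(B, function(slice) {
        slice <- as.matrix(slice)
        storage.mode(slice) <- "double"
        dimnames(slice) <- list(states, states)
        slice
    })
    D <- as.numeric(D)
    names(D) <- states
    new(class, name = name, states = states, observations = observations,
        A = A, B = B, D = D)
}

#' Construct a generative model or generative process
#'
#' @param states character vector of unique hidden-state labels.
#' @param observations character vector of unique observation labels.
#' @param A likelihood matrix, observations by states, column-stochastic:
#'   \code{A[o, s]} is the probability of observing \code{o} in state \code{s}.
#' @param B a single states-by-states transition matrix (taken as one
#'   uncontrolled slice named \code{"advance"}) or a named list of such
#'   matrices, one per action. Column \code{j} is the distribution over the
#'   state at time \code{t} given state \code{j} at time \code{t - 1}.
#' @param D initial state distribution over \code{states}.
#' @param name configuration name.
#' @return a validated [GenerativeModel] (resp. [GenerativeProcess]).
#' @examples
#' m <- generativeModel(
#'     states = c("rounded", "sharp"),
#'     observations = c("crushing", "cutting"),
#'     A = matrix(c(0.9, 0.1, 0.2, 0.8), 2),
#'     B = diag(2), D = c(1, 0), name = "toy")
#' states(m)
#' @export
generativeModel <- function(states, observations, A, B, D, name = "model") {
    .buildModel("GenerativeModel", states, observations, A, B, D, name)
}

#' @rdname generativeModel
#' @export
generativeProcess <- function(states, observations, A, B, D,
                              name = "process") {
    .buildModel("GenerativeProcess", states, observations, A, B, D, name)
}

#' @describeIn generativeModel reinterpret a model's parameters as the true
#'   environmental process (e.g. when agent and environment share parameters).
#' @param model a [GenerativeModel].
#' @export
asGenerativeProcess <- function(model) {
    stopifnot(is(model, "GenerativeModel"))
    new("GenerativeProcess", name = model@name, states = model@states,
        observations = model@observations, A = model@A, B = model@B,
        D = model@D)
}

#' Construct a belief state
#'
#' @param probs numeric vector of state probabilities; if unnamed, names are
#'   taken from \code{states}.
#' @param time non-negative integer time index.
#' @param states optional state labels for an unnamed \code{probs}.
#' @return a [BeliefState].
#' @export
beliefState <- function(probs, time = 0L, states = names(probs)) {
    probs <- as.numeric(stats::setNames(probs, states))
    names(probs) <- states
    new("BeliefState", probs = probs, time = .asCount(time, "time",
                                                     zero_ok = TRUE))
}

#' Construct a count matrix
#'
#' @param rows,cols row and column labels (for an initial-state-shaped count
#'   vector use a single column, e.g. \code{cols = "D"}).
#' @param prior scalar pseudo-count added to every cell, or a full matrix of
#'   prior counts. The default 0 gives pure frequency counting.
#' @param counts optional full matrix of counts (overrides \code{prior}).
#' @return a [CountMatrix].
#' @examples
#' cm <- countMatrix(c("crushing", "cutting"), c("rounded", "sharp"))
#' counts(incrementCounts(cm, "cutting", "sharp"))
#' @export
countMatrix <- function(rows, cols, prior = 0, counts = NULL) {
    .assertLabels(rows, "row labels")
    .assertLabels(cols, "column labels")
    if (is.null(counts)) {
        if (is.matrix(prior)) {
            counts <- prior
        } else {
            stopifnot(length(prior) == 1L, prior >= 0)
            counts <- matrix(prior, length(rows), length(cols))
        }
    }
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    dimnames(counts) <- list(rows, cols)
    new("CountMatrix", counts = counts)
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "GenerativeModel", function(object) {
    cat(class(object), sprintf("'%s'", object@name), "\n")
    cat("  states      (", length(object@states), "): ",
        paste(object@states, collapse = ", "), "\n", sep = "")
    cat("  observations(", length(object@observations), "): ",
        paste(object@observations, collapse = ", "), "\n", sep = "")
    cat("  actions     (", length(object@B), "): ",
        paste(names(object@B), collapse = ", "), "\n", sep = "")
    pA <- environmentalPrecision(object@A)
    cat(sprintf("  A entropy %.4f nats (normalized precision %.4f)\n",
                pA@totalEntropy, pA@normalizedPrecision))
    pB <- environmentalPrecision(object@B[[1L]])
    cat(sprintf("  B[1] entropy %.4f nats (normalized precision %.4f)\n",
                pB@totalEntropy, pB@normalizedPrecision))
})

setMethod("show", "BeliefState", function(object) {
    cat("BeliefState at t =", object@time, "\n")
    print(round(object@probs, 6L))
})

setMethod("show", "PrecisionReport", function(object) {
    cat("PrecisionReport\n")
    cat("  column entropies (nats):",
        paste(sprintf("%.4f", object@columnEntropies), collapse = " "), "\n")
    cat(sprintf("  total entropy: %.6f / max %.6f nats\n",
                object@totalEntropy, object@maxEntropy))
    cat(sprintf("  normalized precision: %.6f\n", object@normalizedPrecision))
})

setMethod("show", "SalienceReport", function(object) {
    cat("SalienceReport\n")
    for (a in names(object@gains))
        cat(sprintf("  %s%s: %.6f nats\n",
                    if (a == object@selected) "* " else "  ",
                    a, object@gains[[a]]))
})

setMethod("show", "CountMatrix", function(object) {
    cat("CountMatrix", nrow(object@counts), "x", ncol(object@counts), "\n")
    print(object@counts)
})

setMethod("show", "BundledConfig", function(object) {
    cat("BundledConfig '", object@name, "'\n", sep = "")
    show(object@model)
})
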