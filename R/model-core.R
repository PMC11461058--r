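#' Joint probability of a state/observation sequence pair
#'
#' Evaluates the model's joint
#' \eqn{P(s_{1:T}, o_{1:T}) = D(s_1) \prod_t A(o_t \mid s_t)
#' \prod_{t \ge 2} B(s_t \mid s_{t-1})}
#' for the given label sequences, using the stated action's transition slice
#' (the first slice by default).
#'
#' @param model a [GenerativeModel] or [GenerativeProcess].
#' @param stateSeq character vector of state labels, length \code{T >= 1}.
#' @param obsSeq character vector of observation labels, same length.
#' @param action action label or index selecting the B slice (default first).
#' @return a single probability in \code{[0, 1]}.
#' @examples
#' fg <- configModel(loadBundled("foraging_grid"))
#' jointProbability(fg, c("up-left", "up-right"), c("blue", "yellow"))
#' @export
jointProbability <- function(model, stateSeq, obsSeq, action = 1L) {
    stopifnot(is(model, "GenerativeModel"))
    if (length(stateSeq) != length(obsSeq))
        stop("stateSeq and obsSeq must have equal length", call. = FALSE)
    if (length(stateSeq) < 1L)
        stop("sequences must have length >= 1", call. = FALSE)
    si <- .matchLabel(stateSeq, model@states, "state")
    oi <- .matchLabel(obsSeq, model@observations, "observation")
    B <- transitions(model, action)
    p <- model@D[si[1L]]
    for (t in seq_along(si)) {
        p <- p * model@A[oi[t], si[t]]
        if (t >= 2L) p <- p * B[si[t], si[t - 1L]]
    }
    unname(p)
}

#' Exact Bayesian filtering over hidden states
#'
#' Runs the forward recursion for a categorical hidden Markov model: the
#' posterior at time \code{t} is proportional to
#' \eqn{A(o_t \mid \cdot) \odot B\,Q_{t-1}} (with \eqn{D} in place of
#' \eqn{B Q_0} at the first step), renormalised at each step.
#'
#' @inheritParams jointProbability
#' @param obsSeq non-empty character vector of observation labels.
#' @return a list of [BeliefState] objects, one per observation, with time
#'   indices \code{1..T}.
#' @details An observation sequence with zero total likelihood under the model
#'   is reported as an error ("degenerate evidence") rather than yielding NaN
#'   posteriors.
#' @examples
#' fg <- configModel(loadBundled("foraging_grid"))
#' beliefProbs(forwardFilter(fg, c("blue", "yellow"))[[2]])
#' @export
forwardFilter <- function(model, obsSeq, action = 1L) {
    stopifnot(is(model, "GenerativeModel"))
    if (length(obsSeq) < 1L)
        stop("obsSeq must be non-empty", call. = FALSE)
    oi <- .matchLabel(obsSeq, model@observations, "observation")
    B <- transitions(model, action)
    out <- vector("list", length(oi))
    prior <- model@D
    for (t in seq_along(oi)) {
        if (t >= 2L) prior <- as.numeric(B %*% post)
        post <- model@A[oi[t], ] * prior
        z <- sum(post)
        if (z <= 0)
            stop("degenerate evidence: observation '", obsSeq[t],
                 "' at step ", t,
                 " has zero likelihood under the model", call. = FALSE)
        post <- post / z
        out[[t]] <- new("BeliefState",
                        probs = stats::setNames(post, model@states),
                        time = t)
    }
    out
}

#' Forecast hidden states over a horizon
#'
#' Propagates a belief forward through the transition matrix without new
#' evidence: \eqn{Q_{t+k} = B^k Q_t}.
#'
#' @inheritParams jointProbability
#' @param belief a [BeliefState].
#' @param horizon number of steps ahead, \code{>= 1}.
#' @return list of [BeliefState] forecasts for \code{1..horizon} steps ahead.
#' @export
predictStates <- function(model, belief, horizon = 1L, action = 1L) {
    stopifnot(is(model, "GenerativeModel"), is(belief, "BeliefState"))
    horizon <- .asCount(horizon, "horizon")
    B <- transitions(model, action)
    q <- belief@probs[model@states]
    if (anyNA(q))
        stop("belief is not indexed by the model's states", call. = FALSE)
    out <- vector("list", horizon)
    for (k in seq_len(horizon)) {
        q <- as.numeric(B %*% q)
        q <- q / sum(q)
        out[[k]] <- new("BeliefState",
                        probs = stats::setNames(q, model@states),
                        time = belief@time + k)
    }
    out
}

#' Predictive distribution over the next observation
#'
#' Marginalises the likelihood over a belief: \eqn{P(o) = A\,Q(s)}.
#'
#' @inheritParams predictStates
#' @return named numeric vector over observations, summing to 1.
#' @export
predictObservations <- function(model, belief) {
    stopifnot(is(model, "GenerativeModel"), is(belief, "BeliefState"))
    q <- belief@probs[model@states]
    if (anyNA(q))
        stop("belief is not indexed by the model's states", call. = FALSE)
    p <- as.numeric(model@A %*% q)
    stats::setNames(p / sum(p), model@observations)
}

#' Simulate a trajectory from a generative process
#'
#' Samples \eqn{s_1 \sim D}, \eqn{s_t \sim B(\cdot \mid s_{t-1})},
#' \eqn{o_t \sim A(\cdot \mid s_t)} for \code{steps} steps. The same
#' \code{seed} always yields the same trajectory; the caller's RNG state is
#' left untouched.
#'
#' @param process a [GenerativeProcess] (the environment's true parameters).
#' @param steps trajectory length, \code{>= 1}.
#' @param seed integer seed for this call.
#' @param action action label or index selecting the B slice.
#' @return a data.frame with columns \code{step}, \code{state},
#'   \code{observation}.
#' @examples
#' fg <- configProcess(loadBundled("foraging_grid"))
#' simulateTrajectory(fg, steps = 2, seed = 1)
#' @export
simulateTrajectory <- function(process, steps, seed, action = 1L) {
    stopifnot(is(process, "GenerativeProcess"))
    steps <- .asCount(steps, "steps")
    B <- transitions(process, action)
    .withSeed(seed, function() {
        s <- character(steps)
        o <- character(steps)
        for (t in seq_len(steps)) {
            prob <- if (t == 1L) process@D else B[, s[t - 1L]]
            s[t] <- .sampleLabel(process@states, prob)
            o[t] <- .sampleLabel(process@observations, process@A[, s[t]])
        }
        data.frame(step = seq_len(steps), state = s, observation = o,
                   stringsAsFactors = FALSE)
    })
}
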