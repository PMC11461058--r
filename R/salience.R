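# Overt attention: epistemic value of candidate actions and the
# perception-action loop that couples it to filtering.

.GAIN_CLAMP <- 1e-12

#' Expected information gain of an action
#'
#' Scores an action by how much it is expected to teach the agent about the
#' hidden state. With predictive state prior \eqn{Q' = B_a Q} and predictive
#' observation distribution \eqn{P(o) = A Q'}, the gain is
#' \deqn{\sum_o P(o)\, KL[\,Q'(\cdot \mid o)\, \| \,Q'\,],}
#' the expected KL divergence between the post-observation posterior and the
#' prior — equivalently the mutual information between next state and next
#' observation under the model. It is 0 when the outcome is already known
#' (one-hot predictive belief) and 0 when the likelihood is uninformative
#' (identical columns), and is bounded above by the entropy of \eqn{Q'}.
#'
#' @param model a [GenerativeModel].
#' @param belief current [BeliefState] over hidden states.
#' @param action action label or index of the B slice the action applies.
#' @return expected information gain in nats (non-negative; round-off below
#'   1e-12 is clamped to 0).
#' @export
expectedInformationGain <- function(model, belief, action = 1L) {
    stopifnot(is(model, "GenerativeModel"), is(belief, "BeliefState"))
    B <- transitions(model, action)
    q <- belief@probs[model@states]
    if (anyNA(q))
        stop("belief is not indexed by the model's states", call. = FALSE)
    qp <- as.numeric(B %*% q)
    qp <- qp / sum(qp)
    po <- as.numeric(model@A %*% qp)
    gain <- 0
    for (o in seq_along(po)) {
        if (po[o] <= 0) next
        post <- model@A[o, ] * qp / po[o]
        nz <- post > 0
        gain <- gain + po[o] * sum(post[nz] * log(post[nz] / qp[nz]))
    }
    if (gain < 0) {
        if (gain < -.GAIN_CLAMP)
            stop("negative information gain beyond round-off: ", gain,
                 call. = FALSE)
        gain <- 0
    }
    gain
}

#' Select the most salient action
#'
#' Computes the expected information gain of every candidate action and picks
#' the maximiser; ties go to the earliest action in \code{actions}.
#'
#' @inheritParams expectedInformationGain
#' @param actions non-empty character vector of action labels (defaults to all
#'   of the model's actions).
#' @return a [SalienceReport].
#' @export
selectSalientAction <- function(model, belief, actions = NULL) {
    stopifnot(is(model, "GenerativeModel"))
    if (is.null(actions)) actions <- names(model@B)
    if (length(actions) < 1L)
        stop("actions must be non-empty", call. = FALSE)
    .matchLabel(unique(actions), names(model@B), "action")
    gains <- vapply(actions, function(a)
        expectedInformationGain(model, belief, a), numeric(1L))
    names(gains) <- actions
    new("SalienceReport", gains = gains,
        selected = actions[which.max(gains)])
}

#' Run a salience-driven perception-action loop
#'
#' Couples overt attention to filtering: at the first step the environment
#' draws an initial state and observation and the agent filters its prior
#' through that evidence; at every later step the agent scores all actions by
#' expected information gain, performs the most salient one, the environment
#' transitions and emits an observation under that action, and the agent
#' updates its belief by Bayes.
#'
#' @param model the agent's [GenerativeModel].
#' @param process the environment's [GenerativeProcess]; must share state,
#'   observation and action labels with \code{model}.
#' @param steps number of time steps, \code{>= 1}.
#' @param seed integer seed (the loop is reproducible in \code{seed}).
#' @return a list of per-step records, each a list with elements \code{step},
#'   \code{action} (\code{NA} at the first step), \code{salience} (a
#'   [SalienceReport], \code{NULL} at the first step), \code{state},
#'   \code{observation} and \code{belief} (a [BeliefState]). Convert to a flat
#'   table with [traceToFrame()].
#' @export
runActiveLoop <- function(model, process, steps, seed) {
    stopifnot(is(model, "GenerativeModel"), is(process, "GenerativeProcess"))
    steps <- .asCount(steps, "steps")
    if (!identical(model@states, process@states) ||
        !identical(model@observations, process@observations) ||
        !identical(names(model@B), names(process@B)))
        stop("model and process must share state, observation and action ",
             "spaces", call. = FALSE)
    .withSeed(seed, function() {
        trace <- vector("list", steps)
        for (t in seq_len(steps)) {
            if (t == 1L) {
                act <- NA_character_
                rep <- NULL
                s <- .sampleLabel(process@states, process@D)
                prior <- model@D
            } else {
                rep <- selectSalientAction(model, belief)
                act <- rep@selected
                s <- .sampleLabel(process@states,
                                  transitions(process, act)[, s])
                prior <- as.numeric(transitions(model, act) %*%
                                        belief@probs)
            }
            o <- .sampleLabel(process@observations, process@A[, s])
            post <- model@A[o, ] * prior
            z <- sum(post)
            if (z <= 0)
                stop("degenerate evidence: observation '", o, "' at step ",
                     t, " has zero likelihood under the model",
                     call. = FALSE)
            belief <- new("BeliefState",
                          probs = stats::setNames(post / z, model@states),
                          time = t)
            trace[[t]] <- list(step = t, action = act, salience = rep,
                               state = s, observation = o, belief = belief)
        }
        trace
    })
}

#' Flatten an active-loop trace to a data.frame
#'
#' @param trace the list returned by [runActiveLoop()].
#' @return a data.frame with columns \code{step}, \code{action},
#'   \code{state}, \code{observation}, one \code{belief.<state>} column per
#'   state, and one \code{gain.<action>} column per action (\code{NA} on the
#'   first step, where no action is scored).
#' @export
traceToFrame <- function(trace) {
    stopifnot(length(trace) >= 1L)
    statesN <- names(trace[[1L]]$belief@probs)
    actN <- NULL
    for (rec in trace)
        if (!is.null(rec$salience)) { actN <- names(rec$salience@gains); break }
    rows <- lapply(trace, function(rec) {
        row <- data.frame(step = rec$step, action = rec$action,
                          state = rec$state, observation = rec$observation,
                          stringsAsFactors = FALSE)
        for (s in statesN)
            row[[paste0("belief.", s)]] <- unname(rec$belief@probs[s])
        for (a in actN)
            row[[paste0("gain.", a)]] <-
                if (is.null(rec$salience)) NA_real_
                else unname(rec$salience@gains[a])
        row
    })
    do.call(rbind, rows)
}
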