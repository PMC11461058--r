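# Internal numerical helpers. Tolerances are strict: inputs that are not
# stochastic within .STOCH_TOL are rejected, never renormalised silently.

.STOCH_TOL <- 1e-9

.assertProb <- function(p, what = "distribution") {
    if (!is.numeric(p) || length(p) < 1L || anyNA(p))
        stop(what, " must be a non-empty numeric vector without NAs",
             call. = FALSE)
    if (any(p < 0))
        stop(what, " has negative entries", call. = FALSE)
    if (abs(sum(p) - 1) > .STOCH_TOL)
        stop(what, " does not sum to 1 within 1e-9 (sum = ",
             format(sum(p), digits = 15L), ")", call. = FALSE)
    invisible(p)
}

.assertColumnStochastic <- function(M, what = "matrix") {
    if (!is.matrix(M) || !is.numeric(M) || anyNA(M))
        stop(what, " must be a numeric matrix without NAs", call. = FALSE)
    if (any(M < 0))
        stop(what, " has negative entries", call. = FALSE)
    bad <- which(abs(colSums(M) - 1) > .STOCH_TOL)
    if (length(bad))
        stop(what, " has non-stochastic column(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    invisible(M)
}

.assertLabels <- function(x, what = "labels") {
    if (!is.character(x) || length(x) < 1L || anyNA(x) || any(!nzchar(x)))
        stop(what, " must be non-empty character strings", call. = FALSE)
    if (anyDuplicated(x))
        stop(what, " must be unique", call. = FALSE)
    invisible(x)
}

# Shannon entropy in nats, with the 0 * log(0) = 0 convention.
.entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p)) + 0  # + 0 avoids IEEE negative zero for empty sums
}

# Run fn() under a transient RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards, so sampling functions are
# pure in (args, seed) and leave no global trace.
.withSeed <- function(seed, fn) {
    seed <- .asCount(seed, "seed", zero_ok = TRUE, negative_ok = TRUE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    fn()
}

.asCount <- function(x, what, zero_ok = FALSE, negative_ok = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
        stop(what, " must be a single integer", call. = FALSE)
    x <- as.integer(x)
    if (!negative_ok && x < 0L) stop(what, " must be >= 0", call. = FALSE)
    if (!zero_ok && !negative_ok && x < 1L)
        stop(what, " must be >= 1", call. = FALSE)
    x
}

.sampleLabel <- function(labels, prob) {
    labels[sample.int(length(labels), 1L, prob = prob)]
}

.matchLabel <- function(x, labels, what) {
    i <- match(x, labels)
    if (anyNA(i))
        stop("unknown ", what, " label(s): ",
             paste(unique(x[is.na(i)]), collapse = ", "), call. = FALSE)
    i
}
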