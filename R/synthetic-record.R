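# Synthetic archaeological records: every other component of the package can
# be exercised against data drawn from a known generative process.

#' Generate a synthetic artefact record
#'
#' Emulates an archaeological record from a known generative process: for each
#' site a shape trajectory is sampled from \eqn{D} then \eqn{B} across
#' periods, and one afforded-function observation is sampled from \eqn{A}
#' given the shape of each period. Each shape and function field is then
#' independently blanked with probability \code{missingness}, mimicking
#' incomplete excavation or undiagnostic finds. Multiple finds per period can
#' be emulated by replicate sites, which keeps the transition tallies
#' well-defined.
#'
#' @param process a [GenerativeProcess].
#' @param nSites,nPeriods number of sites and of periods per site (both
#'   \code{>= 1}); the record has \code{nSites * nPeriods} rows.
#' @param missingness probability in \code{[0, 1)} that any one field is
#'   missing.
#' @param seed integer seed; the record is a pure function of
#'   \code{(process, nSites, nPeriods, missingness, seed)}.
#' @param action action label or index of the B slice driving the shape
#'   trajectories.
#' @return an artefact record data.frame with columns \code{site_id},
#'   \code{period} (0-based), \code{shape}, \code{function}.
#' @examples
#' kp <- configProcess(loadBundled("knapping_tool_deterministic"))
#' generateRecord(kp, nSites = 2, nPeriods = 3, seed = 1)
#' @export
generateRecord <- function(process, nSites, nPeriods, missingness = 0,
                           seed, action = 1L) {
    stopifnot(is(process, "GenerativeProcess"))
    nSites <- .asCount(nSites, "nSites")
    nPeriods <- .asCount(nPeriods, "nPeriods")
    if (!is.numeric(missingness) || length(missingness) != 1L ||
        is.na(missingness) || missingness < 0 || missingness >= 1)
        stop("missingness must lie in [0, 1)", call. = FALSE)
    B <- transitions(process, action)
    .withSeed(seed, function() {
        n <- nSites * nPeriods
        site <- rep(sprintf("site%04d", seq_len(nSites)), each = nPeriods)
        period <- rep(seq_len(nPeriods) - 1L, times = nSites)
        shape <- character(n)
        fn <- character(n)
        idx <- 0L
        for (i in seq_len(nSites)) {
            prev <- NULL
            for (p in seq_len(nPeriods)) {
                idx <- idx + 1L
                prob <- if (is.null(prev)) process@D else B[, prev]
                prev <- .sampleLabel(process@states, prob)
                shape[idx] <- prev
                fn[idx] <- .sampleLabel(process@observations,
                                        process@A[, prev])
            }
        }
        if (missingness > 0) {
            shape[stats::runif(n) < missingness] <- NA_character_
            fn[stats::runif(n) < missingness] <- NA_character_
        }
        artefactRecord(site, period, shape, fn,
                       states = process@states,
                       observations = process@observations)
    })
}

#' Degrade the environmental precision of a parameter matrix
#'
#' Mixes every column of a column-stochastic matrix toward the uniform
#' distribution: column \eqn{j} becomes
#' \eqn{(1 - \lambda)\,M_{\cdot j} + \lambda / K}. The operation is
#' deterministic, anchors \eqn{\lambda = 0} (unchanged) and \eqn{\lambda = 1}
#' (all-uniform), and — by concavity of entropy — never decreases the
#' matrix's environmental entropy as \eqn{\lambda} grows. It models an
#' environment whose signal has been blurred (road lines under snow or sand):
#' the mapping is still there, but affords less precise information.
#'
#' @param M a column-stochastic matrix.
#' @param noiseLevel mixing weight \eqn{\lambda} in \code{[0, 1]}.
#' @return a column-stochastic matrix of the same shape and dimnames.
#' @examples
#' degradePrecision(diag(2), 0.5)   # columns 0.75 / 0.25
#' @export
degradePrecision <- function(M, noiseLevel) {
    .assertColumnStochastic(M, "matrix")
    if (!is.numeric(noiseLevel) || length(noiseLevel) != 1L ||
        is.na(noiseLevel) || noiseLevel < 0 || noiseLevel > 1)
        stop("noiseLevel must lie in [0, 1]", call. = FALSE)
    (1 - noiseLevel) * M + noiseLevel / nrow(M)
}
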