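#' Assemble and validate an artefact record
#'
#' An artefact record tabulates excavated evidence: one row per find, with the
#' site it came from, its (relative) period, the shape of the artefact and the
#' function its use context indicates. Either of \code{shape} and
#' \code{function} may be missing (\code{NA}); missing fields are simply
#' skipped by the tallies that need them.
#'
#' @param site_id character vector of site identifiers.
#' @param period non-negative integer periods (larger = later).
#' @param shape state labels or \code{NA}.
#' @param fun observation labels or \code{NA} (stored in a column named
#'   \code{"function"}).
#' @param states,observations optional label spaces; when supplied, non-missing
#'   labels are checked against them.
#' @return a data.frame with columns \code{site_id}, \code{period},
#'   \code{shape}, \code{function}.
#' @export
artefactRecord <- function(site_id, period, shape, fun,
                           states = NULL, observations = NULL) {
    n <- length(site_id)
    stopifnot(length(period) == n, length(shape) == n, length(fun) == n)
    period <- as.integer(period)
    if (anyNA(period) || any(period < 0L))
        stop("periods must be non-negative integers", call. = FALSE)
    rec <- data.frame(site_id = as.character(site_id), period = period,
                      shape = as.character(shape),
                      check.names = FALSE, stringsAsFactors = FALSE)
    rec[["function"]] <- as.character(fun)
    .checkRecord(rec, states, observations)
    rec
}

.checkRecord <- function(record, states = NULL, observations = NULL) {
    need <- c("site_id", "period", "shape", "function")
    if (!is.data.frame(record) || !all(need %in% names(record)))
        stop("record must have columns site_id, period, shape, function",
             call. = FALSE)
    if (anyNA(record$period) || any(record$period < 0))
        stop("periods must be non-negative", call. = FALSE)
    if (!is.null(states)) {
        sh <- record$shape[!is.na(record$shape)]
        if (length(sh)) .matchLabel(sh, states, "state")
    }
    if (!is.null(observations)) {
        fn <- record[["function"]][!is.na(record[["function"]])]
        if (length(fn)) .matchLabel(fn, observations, "observation")
    }
    invisible(record)
}

#' Add evidence weight to one cell of a count matrix
#'
#' The count-based update rule: a piece of evidence for the mapping in cell
#' \code{(row, col)} raises that cell's weight by \code{weight} (by default
#' +1), leaving every other cell untouched. Evidence strength need not be
#' integral — weaker, non-empirical evidence can be added with a fractional
#' weight.
#'
#' @param cm a [CountMatrix].
#' @param row,col cell coordinates, as labels or indices.
#' @param weight positive evidence weight.
#' @return the updated [CountMatrix].
#' @examples
#' cm <- countMatrix(c("crushing", "cutting"), "sharp",
#'                   counts = matrix(c(0.3, 0.7), 2, 1))
#' counts(incrementCounts(cm, "crushing", "sharp"))[1, 1]  # 0.3 -> 1.3
#' @export
incrementCounts <- function(cm, row, col, weight = 1) {
    stopifnot(is(cm, "CountMatrix"))
    if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
        weight <= 0)
        stop("weight must be a single positive number", call. = FALSE)
    M <- cm@counts
    i <- if (is.character(row)) .matchLabel(row, rownames(M), "row") else row
    j <- if (is.character(col)) .matchLabel(col, colnames(M), "column") else col
    if (!is.numeric(i) || i < 1 || i > nrow(M) ||
        !is.numeric(j) || j < 1 || j > ncol(M))
        stop("cell (", row, ", ", col, ") is out of range", call. = FALSE)
    M[i, j] <- M[i, j] + weight
    cm@counts <- M
    cm
}

#' Normalise a count matrix into a column-stochastic parameter
#'
#' Divides each column by its sum, so that accumulated evidence weights become
#' a likelihood matrix, transition slice, or (for one column) an initial-state
#' distribution. Normalisation is only defined when every column has positive
#' total weight.
#'
#' @param cm a [CountMatrix] (or a bare non-negative matrix).
#' @return a column-stochastic numeric matrix with the same dimnames.
#' @examples
#' normalizeCounts(countMatrix(c("a", "b"), "s",
#'                 counts = matrix(c(1.3, 0.7), 2, 1)))  # 0.65, 0.35
#' @export
normalizeCounts <- function(cm) {
    M <- if (is(cm, "CountMatrix")) cm@counts else as.matrix(cm)
    if (any(M < 0))
        stop("counts must be non-negative", call. = FALSE)
    cs <- colSums(M)
    zero <- which(cs <= 0)
    if (length(zero)) {
        lab <- if (!is.null(colnames(M))) colnames(M)[zero] else zero
        stop("cannot normalize: zero-sum column(s) ",
             paste(lab, collapse = ", "), call. = FALSE)
    }
    sweep(M, 2L, cs, "/")
}

#' Tally model parameters from an artefact record
#'
#' Accumulates evidence counts for the three parameters of an artefact model
#' from a tabulated record:
#' \itemize{
#'   \item A: each row with both shape and function present adds
#'     \code{+1} to \code{A[function, shape]} — functions co-occurring with
#'     shapes in the record parameterise the shape-to-function likelihood;
#'   \item B: within each site, each pair of rows at consecutive periods
#'     (difference exactly 1) with both shapes present adds \code{+1} to
#'     \code{B[shape_t, shape_t-1]}; gaps contribute nothing;
#'   \item D: each site's earliest-period row with a shape present adds
#'     \code{+1} to \code{D[shape]}.
#' }
#' Counts are added on top of the supplied priors (default 0, i.e. pure
#' frequency). Normalise with [normalizeCounts()] to obtain the parameters.
#'
#' @param record an artefact record data.frame (see [artefactRecord()]).
#' @param states hidden-state (shape) labels.
#' @param observations observation (function) labels.
#' @param priorA,priorB,priorD scalar pseudo-count per cell, or a full prior
#'   matrix of the right shape.
#' @return list with [CountMatrix] elements \code{A} (observations x states),
#'   \code{B} (states x states) and \code{D} (states x 1).
#' @examples
#' rec <- artefactRecord(rep("s1", 3), 0:2,
#'                       c("rounded", "squared", "sharp"),
#'                       c("crushing", "cracking", "cutting"))
#' tal <- learnFromRecord(rec, c("rounded", "squared", "sharp"),
#'                        c("crushing", "cracking", "cutting"))
#' counts(tal$B)
#' @export
learnFromRecord <- function(record, states, observations,
                            priorA = 0, priorB = 0, priorD = 0) {
    .assertLabels(states, "state labels")
    .assertLabels(observations, "observation labels")
    .checkRecord(record, states, observations)

    A <- countMatrix(observations, states, prior = priorA)@counts
    B <- countMatrix(states, states, prior = priorB)@counts
    D <- countMatrix(states, "D", prior = priorD)@counts

    shape <- record$shape
    fn <- record[["function"]]
    # A: complete (shape, function) rows
    ok <- !is.na(shape) & !is.na(fn)
    if (any(ok)) {
        tab <- table(factor(fn[ok], levels = observations),
                     factor(shape[ok], levels = states))
        A <- A + unclass(tab)
    }
    # B and D: per-site trajectories ordered by period
    for (site in unique(record$site_id)) {
        rows <- record[record$site_id == site, , drop = FALSE]
        rows <- rows[order(rows$period), , drop = FALSE]
        sh <- rows$shape
        pd <- rows$period
        earliest <- which(pd == min(pd) & !is.na(sh))
        for (k in earliest)
            D[sh[k], 1L] <- D[sh[k], 1L] + 1
        if (nrow(rows) >= 2L) {
            for (k in 2:nrow(rows)) {
                if (pd[k] - pd[k - 1L] == 1L &&
                    !is.na(sh[k]) && !is.na(sh[k - 1L]))
                    B[sh[k], sh[k - 1L]] <- B[sh[k], sh[k - 1L]] + 1
            }
        }
    }
    list(A = countMatrix(observations, states, counts = A),
         B = countMatrix(states, states, counts = B),
         D = countMatrix(states, "D", counts = D))
}
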