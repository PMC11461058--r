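# Plain-text serialisation: model JSON, matrix CSV, record and trajectory TSV.
# Matrices are stored column-wise (each inner array is one categorical
# distribution), matching the column-distribution convention everywhere else.

.modelToList <- function(model) {
    list(
        name = model@name,
        states = as.list(model@states),
        observations = as.list(model@observations),
        A = lapply(seq_len(ncol(model@A)),
                   function(j) as.list(unname(model@A[, j]))),
        actions = as.list(names(model@B)),
        B = lapply(model@B, function(slice)
            lapply(seq_len(ncol(slice)),
                   function(j) as.list(unname(slice[, j])))),
        D = as.list(unname(model@D))
    )
}

.colsToMatrix <- function(cols, nrow, what) {
    vals <- lapply(cols, function(col) vapply(col, as.numeric, numeric(1L)))
    if (any(vapply(vals, length, integer(1L)) != nrow))
        stop(what, ": column length mismatch", call. = FALSE)
    do.call(cbind, vals)
}

#' Read and write model specifications as JSON
#'
#' The JSON layout has keys \code{name}, \code{states}, \code{observations},
#' \code{A} (array of columns, each a distribution over observations),
#' \code{actions}, \code{B} (array of slices, each an array of columns over
#' states) and \code{D}. Values representable in decimal round-trip exactly,
#' and write-read-write is byte-identical.
#'
#' @param model a [GenerativeModel] or [GenerativeProcess].
#' @param path file path.
#' @param process if \code{TRUE}, \code{readModel} returns a
#'   [GenerativeProcess].
#' @return \code{readModel} returns the model object; \code{writeModel}
#'   returns \code{path} invisibly.
#' @export
writeModel <- function(model, path) {
    stopifnot(is(model, "GenerativeModel"))
    jsonlite::write_json(.modelToList(model), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path, process = FALSE) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    need <- c("name", "states", "observations", "A", "B", "D")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("model JSON '", path, "' is missing key(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    states <- vapply(x$states, as.character, character(1L))
    obs <- vapply(x$observations, as.character, character(1L))
    A <- .colsToMatrix(x$A, length(obs), "A")
    slices <- lapply(x$B, .colsToMatrix, nrow = length(states), what = "B")
    names(slices) <- if (!is.null(x$actions))
        vapply(x$actions, as.character, character(1L))
    else paste0("action", seq_along(slices))
    D <- vapply(x$D, as.numeric, numeric(1L))
    builder <- if (process) generativeProcess else generativeModel
    builder(states, obs, A, slices, D, name = as.character(x$name))
}

#' Read and write a single matrix as labelled CSV
#'
#' Column labels (states) form the header row; row labels (observations, or
#' previous-period states for a transition slice) form the first column.
#'
#' @param M a numeric matrix with dimnames.
#' @param path file path.
#' @return \code{readMatrixCSV} returns the matrix; \code{writeMatrixCSV}
#'   returns \code{path} invisibly.
#' @export
writeMatrixCSV <- function(M, path) {
    stopifnot(is.matrix(M))
    df <- data.frame(label = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("matrix CSV '", path, "' needs a label column plus data",
             call. = FALSE)
    M <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- as.character(df[[1L]])
    M
}

#' Read and write artefact records as TSV
#'
#' Tab-separated with header \code{site_id}, \code{period}, \code{shape},
#' \code{function}; an empty cell is a missing field. A record written and
#' re-read is identical.
#'
#' @param record an artefact record data.frame (see [artefactRecord()]).
#' @param path file path.
#' @return \code{readRecord} returns the record; \code{writeRecord} returns
#'   \code{path} invisibly.
#' @export
writeRecord <- function(record, path) {
    .checkRecord(record)
    utils::write.table(record[c("site_id", "period", "shape", "function")],
                       path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeRecord
#' @export
readRecord <- function(path) {
    df <- utils::read.delim(path, sep = "\t", na.strings = "",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = c("character", "integer",
                                           "character", "character"))
    .checkRecord(df)
    df
}

#' Read and write simulated trajectories as TSV
#'
#' Columns \code{step}, \code{state}, \code{observation}.
#'
#' @param trajectory data.frame as returned by [simulateTrajectory()].
#' @param path file path.
#' @return \code{readTrajectory} returns the data.frame; \code{writeTrajectory}
#'   returns \code{path} invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
    stopifnot(all(c("step", "state", "observation") %in% names(trajectory)))
    utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
    utils::read.delim(path, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
}
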