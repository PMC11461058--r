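# Bundled worked configurations: a 2x2 visual-foraging grid and the
# knapping-tool artefact model in its high-precision (deterministic) and
# zero-precision (uniform) variants. Constructed in code so they are always
# validated at load time.

.onehot <- function(labels, at) {
    p <- stats::setNames(numeric(length(labels)), labels)
    p[at] <- 1
    p
}

.detMatrix <- function(rows, cols, map) {
    M <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    for (j in names(map)) M[map[[j]], j] <- 1
    M
}

.foragingGrid <- function(controlled = FALSE) {
    locs <- c("up-left", "up-right", "down-left", "down-right")
    cols <- c("blue", "yellow", "red", "green")
    # each location deterministically affords one colour
    A <- .detMatrix(cols, locs, list("up-left" = "blue",
                                     "up-right" = "yellow",
                                     "down-left" = "red",
                                     "down-right" = "green"))
    if (controlled) {
        # one movement action per location: go there from anywhere
        B <- lapply(locs, function(target) {
            M <- matrix(0, length(locs), length(locs),
                        dimnames = list(locs, locs))
            M[target, ] <- 1
            M
        })
        names(B) <- paste0("move-", locs)
        name <- "foraging_grid_controlled"
    } else {
        # uncontrolled reading-order cycle UL -> UR -> DL -> DR -> UL
        B <- list(advance = .detMatrix(locs, locs,
            list("up-left" = "up-right", "up-right" = "down-left",
                 "down-left" = "down-right", "down-right" = "up-left")))
        name <- "foraging_grid"
    }
    D <- .onehot(locs, "up-left")
    model <- generativeModel(locs, cols, A, B, D, name = name)
    new("BundledConfig", name = name, model = model,
        process = asGenerativeProcess(model))
}

.knappingTool <- function(variant = c("deterministic", "uniform")) {
    variant <- match.arg(variant)
    shapes <- c("rounded", "squared", "sharp")
    fns <- c("crushing", "cracking", "cutting")
    if (variant == "deterministic") {
        A <- .detMatrix(fns, shapes, list("rounded" = "crushing",
                                          "squared" = "cracking",
                                          "sharp" = "cutting"))
        # shape progression round -> square -> sharp, sharp absorbing
        B <- .detMatrix(shapes, shapes, list("rounded" = "squared",
                                             "squared" = "sharp",
                                             "sharp" = "sharp"))
        D <- .onehot(shapes, "rounded")
    } else {
        A <- matrix(1 / 3, 3, 3, dimnames = list(fns, shapes))
        B <- matrix(1 / 3, 3, 3, dimnames = list(shapes, shapes))
        D <- stats::setNames(rep(1 / 3, 3), shapes)
    }
    name <- paste0("knapping_tool_", variant)
    model <- generativeModel(shapes, fns, A, list(advance = B), D,
                             name = name)
    new("BundledConfig", name = name, model = model,
        process = asGenerativeProcess(model))
}

#' Load a bundled configuration
#'
#' Available names:
#' \describe{
#'   \item{\code{"foraging_grid"}}{2x2 visual-foraging grid with locations
#'     \code{up-left}, \code{up-right}, \code{down-left}, \code{down-right}
#'     deterministically affording \code{blue}, \code{yellow}, \code{red},
#'     \code{green}; a single uncontrolled transition cycling the grid in
#'     reading order; start at \code{up-left}.}
#'   \item{\code{"foraging_grid_controlled"}}{same grid with four movement
#'     actions (\code{move-up-left}, ...), each taking the agent to its
#'     target location from anywhere, for salience-driven exploration.}
#'   \item{\code{"knapping_tool_deterministic"}}{3 shapes
#'     (\code{rounded}, \code{squared}, \code{sharp}) affording 3 functions
#'     (\code{crushing}, \code{cracking}, \code{cutting}) with fully
#'     deterministic A and B (shape progression rounded to squared to sharp,
#'     sharp absorbing): environmental precision 1.}
#'   \item{\code{"knapping_tool_uniform"}}{same spaces with all-uniform A and
#'     B: environmental precision 0.}
#'   \item{\code{"knapping_tool"}}{alias for the deterministic variant.}
#' }
#'
#' @param name one of the registry names above.
#' @return a [BundledConfig] whose model and process share parameters.
#' @examples
#' cfg <- loadBundled("knapping_tool_deterministic")
#' totalEntropy(environmentalPrecision(configModel(cfg), matrix = "A"))
#' @export
loadBundled <- function(name) {
    switch(name,
        foraging_grid = .foragingGrid(FALSE),
        foraging_grid_controlled = .foragingGrid(TRUE),
        knapping_tool = ,
        knapping_tool_deterministic = .knappingTool("deterministic"),
        knapping_tool_uniform = .knappingTool("uniform"),
        stop("unknown bundled configuration '", name, "'; available: ",
             "foraging_grid, foraging_grid_controlled, ",
             "knapping_tool_deterministic, knapping_tool_uniform",
             call. = FALSE)
    )
}
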