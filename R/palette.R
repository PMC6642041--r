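#' The fixed eight-class tissue label schema
#'
#' The workflow distinguishes six "main" tissue classes — tumor (TUM), mouse
#' stroma/connective tissue (MST), necrosis (NEC), blood cells/vessels (BLC),
#' vacuoles (VAC) and muscle (MUS) — plus technical artifacts (TAR) and
#' background (BGR). Label ids are 0-based (0..7) so that label images round-trip
#' through 8-bit PNG without remapping. Display colors follow the standard
#' rendering convention: red TUM, blue MST, yellow NEC, green BLC, cyan VAC,
#' magenta MUS, black TAR, white BGR.
#'
#' @return A data frame of class `class_palette` with columns `id` (integer,
#'   0..7), `name` (character) and `r`, `g`, `b` (numeric in \[0, 1\]).
#' @examples
#' pal <- make_palette()
#' pal[pal$name == "NEC", ]
#' @export
make_palette <- function() {
  pal <- data.frame(
    id   = 0:7,
    name = c("TUM", "MST", "NEC", "BLC", "VAC", "MUS", "TAR", "BGR"),
    r    = c(1, 0, 1, 0, 0, 1, 0, 1),
    g    = c(0, 0, 1, 1, 1, 0, 0, 1),
    b    = c(0, 1, 0, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE
  )
  class(pal) <- c("class_palette", "data.frame")
  pal
}

#' Display colors of a palette as a matrix
#'
#' @param palette A palette from [make_palette()].
#' @return An 8 x 3 numeric matrix, rows in id order 0..7, columns R, G, B.
#' @export
palette_colors <- function(palette = make_palette()) {
  m <- as.matrix(palette[, c("r", "g", "b")])
  rownames(m) <- palette$name
  m
}

#' Ids of the six main tissue classes
#'
#' TAR (artifacts) and BGR (background) are excluded from tissue-area
#' computations; the remaining six classes are the "main" classes.
#'
#' @return Integer vector of label ids.
#' @export
main_class_ids <- function() 0:5

#' Number of tissue classes
#' @return The integer 8.
#' @export
n_classes <- function() 8L

class_id <- function(name, palette = make_palette()) {
  palette$id[match(name, palette$name)]
}

stopifnot_labels <- function(labels) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("labels must be a non-empty integer matrix")
  if (any(labels < 0L | labels > 7L))
    stop("label values must lie in 0..7")
  invisible(labels)
}
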