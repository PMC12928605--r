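#' Spot coordinate table
#'
#' A `spot_table` holds the spatial capture locations ("spots") of a
#' sequencing-based spatial transcriptomics section: one unique identifier
#' per spot and a 2D coordinate in arbitrary length units. It is the input
#' to all graph-construction functions.
#'
#' @param spot_id Character vector of unique spot identifiers.
#' @param coords Numeric matrix with one row per spot and two columns
#'   (x, y). All values must be finite.
#' @return An object of class `spot_table` with elements `spot_id` and
#'   `coords`.
#' @examples
#' st <- spot_table(c("a", "b", "c"), cbind(c(0, 1, 3), 0))
#' n_spots(st)
#' @export
spot_table <- function(spot_id, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("coords must have exactly 2 columns (x, y); got ", ncol(coords))
  n <- nrow(coords)
  if (n < 2L)
    stop("a spot_table needs at least 2 spots; got ", n)
  spot_id <- as.character(spot_id)
  if (length(spot_id) != n)
    stop("length(spot_id) [", length(spot_id), "] != nrow(coords) [", n, "]")
  if (anyDuplicated(spot_id))
    stop("spot_id values must be unique")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  dimnames(coords) <- list(spot_id, c("x", "y"))
  structure(list(spot_id = spot_id, coords = coords), class = "spot_table")
}

#' @rdname spot_table
#' @param x A `spot_table`.
#' @export
n_spots <- function(x) {
  stopifnot(inherits(x, "spot_table"))
  nrow(x$coords)
}

#' @export
print.spot_table <- function(x, ...) {
  cat("spot_table:", n_spots(x), "spots\n")
  cat("  x range:", paste(signif(range(x$coords[, 1]), 5), collapse = " .. "), "\n")
  cat("  y range:", paste(signif(range(x$coords[, 2]), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' Read / write spot coordinates as TSV
#'
#' The on-disk format is a tab-separated file with header columns
#' `spot_id`, `x`, `y`.
#'
#' @param path File path.
#' @return `read_spot_table` returns a [spot_table]; `write_spot_table`
#'   returns `path` invisibly.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("coordinate TSV must have columns spot_id, x, y; found: ",
         paste(names(df), collapse = ", "))
  spot_table(df$spot_id, cbind(x = df$x, y = df$y))
}

#' @rdname read_spot_table
#' @param spots A [spot_table].
#' @export
write_spot_table <- function(spots, path) {
  stopifnot(inherits(spots, "spot_table"))
  df <- data.frame(spot_id = spots$spot_id,
                   x = spots$coords[, 1], y = spots$coords[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
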