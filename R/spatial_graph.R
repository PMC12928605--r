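#' Relative distance computation
#'
#' Computes pairwise Euclidean distances between spots and rescales them by
#' the section's mean nearest-neighbour distance. For spots i, j with
#' coordinates p_i, p_j the raw distance is d0_ij = ||p_i - p_j||_2, the
#' scale is d_bar_min = mean_i min_{j != i} d0_ij, and the relative
#' distance is
#'
#'   d_rel(i, j) = 1 + d0_ij / d_bar_min.
#'
#' The additive constant forces d_rel(i, i) = 1 and d_rel(i, j) > 1 for
#' i != j, so the self-distance is always the smallest: inverse-distance
#' weights built on d_rel keep the self-loop dominant, and the scaling by
#' d_bar_min makes the result invariant to the platform's spot pitch.
#'
#' @param spots A [spot_table].
#' @param on_duplicates What to do when two spots share identical
#'   coordinates (which makes the nearest-neighbour scale degenerate):
#'   `"error"` (default) aborts; `"jitter"` adds uniform jitter of
#'   `1e-6 * d_bar_min` (computed on the non-degenerate pairs) and recomputes.
#' @return An object of class `relative_distances`: a list with `d0`
#'   (N x N raw distances), `d_bar_min` (positive scalar) and `d_rel`
#'   (N x N relative distances, unit diagonal).
#' @examples
#' st <- spot_table(c("a", "b"), cbind(c(0, 0), c(0, 1)))
#' compute_relative_distances(st)$d_rel   # [[1,2],[2,1]]
#' @export
compute_relative_distances <- function(spots, on_duplicates = c("error", "jitter")) {
  stopifnot(inherits(spots, "spot_table"))
  on_duplicates <- match.arg(on_duplicates)
  d0 <- as.matrix(stats::dist(spots$coords))
  dimnames(d0) <- NULL
  nn <- apply(d0 + diag(Inf, nrow(d0)), 1L, min)
  if (any(nn == 0)) {
    if (on_duplicates == "error")
      stop("duplicate coordinates detected: some spots have a zero ",
           "nearest-neighbour distance, which makes the mean ",
           "nearest-neighbour scale degenerate. Deduplicate the input or ",
           "use on_duplicates = \"jitter\".")
    scale0 <- mean(nn[nn > 0])
    if (!is.finite(scale0) || scale0 <= 0)
      stop("all spots are coincident; cannot jitter")
    coords <- spots$coords +
      matrix(stats::runif(2L * nrow(spots$coords), -1, 1) * 1e-6 * scale0,
             ncol = 2L)
    return(compute_relative_distances(spot_table(spots$spot_id, coords),
                                      on_duplicates = "error"))
  }
  d_bar_min <- mean(nn)
  d_rel <- 1 + d0 / d_bar_min
  diag(d_rel) <- 1
  structure(list(d0 = d0, d_bar_min = d_bar_min, d_rel = d_rel),
            class = "relative_distances")
}

#' Asymmetric k-nearest-neighbour graph
#'
#' Connects each spot to its k nearest other spots by Euclidean distance.
#' No symmetrization is applied: j being among i's nearest neighbours does
#' not imply the converse, so the graph retains directional neighbour
#' relationships. Self-loops are recorded separately (`include_self`) and
#' are always present downstream. Ties in distance are broken by ascending
#' spot index so the graph is reproducible across platforms.
#'
#' @param spots A [spot_table].
#' @param k Positive integer number of neighbours. Values above N - 1 are
#'   truncated to N - 1 with a warning.
#' @return An object of class `neighbor_graph`: list with `neighbor_lists`
#'   (integer indices, each of length min(k, N-1), ordered nearest first),
#'   `k` (the effective k) and `include_self = TRUE`.
#' @export
build_knn_graph <- function(spots, k) {
  stopifnot(inherits(spots, "spot_table"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single positive integer")
  n <- n_spots(spots)
  if (k > n - 1L) {
    warning("k = ", k, " exceeds N - 1 = ", n - 1L, "; truncating")
    k <- n - 1L
  }
  d0 <- as.matrix(stats::dist(spots$coords))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d0[i, ], seq_len(n))   # ties broken by ascending index
    ord <- ord[ord != i]
    nb[[i]] <- ord[seq_len(k)]
  }
  structure(list(neighbor_lists = nb, k = k, include_self = TRUE),
            class = "neighbor_graph")
}

new_adjacency <- function(mat, kind, k, p = NA_real_) {
  structure(list(matrix = mat, kind = kind, k = k, p = p),
            class = "dw_adjacency")
}

#' @export
print.dw_adjacency <- function(x, ...) {
  cat("adjacency [", x$kind, "]: ", nrow(x$matrix), " x ", ncol(x$matrix),
      ", k = ", x$k, if (!is.na(x$p)) paste0(", p = ", x$p), "\n", sep = "")
  invisible(x)
}

#' Inverse-distance edge weights
#'
#' Assigns each retained edge the weight d_rel^(-p), where d_rel is the
#' relative distance and p >= 0 a tunable exponent controlling how fast
#' influence decays with distance. Since d_rel(i, i) = 1, every self-loop
#' has weight exactly 1 regardless of p; since d_rel(i, j) > 1 off the
#' diagonal, all neighbour weights are below 1 and shrink as p grows. At
#' p = 0 every stored entry equals 1 (uniform weighting within each
#' neighbourhood).
#'
#' @param graph A `neighbor_graph` from [build_knn_graph()].
#' @param dists A `relative_distances` object from
#'   [compute_relative_distances()] covering the same spots.
#' @param p Non-negative decay exponent.
#' @return A `dw_adjacency` of kind `"raw_idw"` holding a sparse N x N
#'   [Matrix::dgCMatrix-class] with min(k, N-1) + 1 nonzeros per row
#'   (neighbours plus the self-loop).
#' @export
idw_weights <- function(graph, dists, p) {
  stopifnot(inherits(graph, "neighbor_graph"),
            inherits(dists, "relative_distances"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0)
    stop("p must be a single non-negative number")
  n <- length(graph$neighbor_lists)
  if (nrow(dists$d_rel) != n)
    stop("graph and distances disagree on the number of spots")
  deg <- lengths(graph$neighbor_lists)
  ii <- c(rep.int(seq_len(n), deg), seq_len(n))      # edges then self-loops
  jj <- c(unlist(graph$neighbor_lists, use.names = FALSE), seq_len(n))
  w <- dists$d_rel[cbind(ii, jj)]^(-p)
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  new_adjacency(mat, "raw_idw", graph$k, p)
}

#' Row normalization of a weighted adjacency
#'
#' Divides each row of the raw inverse-distance-weighted adjacency by its
#' own sum, producing a row-stochastic matrix. Unlike symmetric degree
#' normalization this is a purely local (spot-wise) operation: the relative
#' ordering of a spot's outgoing weights is preserved, each spot's outgoing
#' mass sums to exactly 1, and high-degree hubs cannot inflate their
#' incoming influence. The result is the propagation operator used in the
#' distance-weighted GCN layer.
#'
#' @param raw A `dw_adjacency` of kind `"raw_idw"`.
#' @return A `dw_adjacency` of kind `"dw_row_normalized"`, same sparsity
#'   pattern, every row summing to 1 within 1e-9.
#' @export
row_normalize <- function(raw) {
  stopifnot(inherits(raw, "dw_adjacency"))
  if (raw$kind != "raw_idw")
    stop("row_normalize expects a raw_idw adjacency; got ", raw$kind)
  rs <- Matrix::rowSums(raw$matrix)
  if (any(rs == 0))
    stop("zero row sum encountered; self-loops should make this unreachable")
  mat <- Matrix::Diagonal(x = 1 / rs) %*% raw$matrix
  mat <- methods::as(mat, "CsparseMatrix")
  rs2 <- Matrix::rowSums(mat)
  stopifnot(all(abs(rs2 - 1) < 1e-9))
  new_adjacency(mat, "dw_row_normalized", raw$k, raw$p)
}

#' Distance-weighted adjacency (one call)
#'
#' Composes the full construction: relative distances, asymmetric KNN graph
#' with self-loops, inverse-distance weights with exponent `p`, and
#' row normalization. Deterministic given the input; invariant to a global
#' rescaling of the coordinates.
#'
#' @inheritParams build_knn_graph
#' @inheritParams idw_weights
#' @param on_duplicates Passed to [compute_relative_distances()].
#' @return A `dw_adjacency` of kind `"dw_row_normalized"`.
#' @examples
#' st <- make_lattice(lattice_spec("hexagonal", n_rows = 9, n_cols = 9))
#' a <- build_dw_adjacency(st, k = 12, p = 2)
#' range(Matrix::rowSums(a$matrix))   # all 1
#' @export
build_dw_adjacency <- function(spots, k = 12, p = 2,
                               on_duplicates = c("error", "jitter")) {
  dists <- compute_relative_distances(spots, on_duplicates = on_duplicates)
  graph <- build_knn_graph(spots, k)
  row_normalize(idw_weights(graph, dists, p))
}

#' Conventional symmetric degree-normalized adjacency
#'
#' The baseline construction used by most spatial GCN workflows: a binary
#' KNN graph symmetrized by the union rule (an edge i-j exists whenever
#' either spot is in the other's KNN set), self-loops added, then symmetric
#' degree normalization
#'
#'   A_tilde = D^(-1/2) (A + I) D^(-1/2),  D_ii = sum_j (A + I)_ij.
#'
#' Every edge weight becomes 1 / sqrt(d_i d_j); on a regular lattice where
#' all interior degrees equal k + 1 this collapses to the uniform value
#' 1 / (k + 1), which is precisely the distance-blindness the
#' distance-weighted construction is designed to avoid.
#'
#' @inheritParams build_knn_graph
#' @return A `dw_adjacency` of kind `"sym_degree_normalized"`; the matrix
#'   is exactly symmetric with entries in [0, 1].
#' @export
build_baseline_adjacency <- function(spots, k = 12) {
  graph <- build_knn_graph(spots, k)
  n <- length(graph$neighbor_lists)
  deg <- lengths(graph$neighbor_lists)
  ii <- rep.int(seq_len(n), deg)
  jj <- unlist(graph$neighbor_lists, use.names = FALSE)
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  a <- methods::as((a + Matrix::t(a)) > 0, "dMatrix")   # union symmetrization
  a <- a + Matrix::Diagonal(n)                          # self-loops
  d <- Matrix::rowSums(a)
  dinv <- Matrix::Diagonal(x = 1 / sqrt(d))
  mat <- methods::as(dinv %*% a %*% dinv, "CsparseMatrix")
  mat <- Matrix::forceSymmetric(mat)
  mat <- methods::as(mat, "generalMatrix")
  new_adjacency(mat, "sym_degree_normalized", graph$k)
}
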