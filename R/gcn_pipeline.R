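#' Preprocess a count matrix into GCN input features
#'
#' Standard spatial-transcriptomics preprocessing: library-size
#' normalization to the median depth, log1p transform, selection of the
#' most variable genes, and projection onto leading principal components.
#'
#' @param counts N x M count matrix (spots in rows).
#' @param n_top_genes Number of highly variable genes kept (by log-scale
#'   variance); capped at M.
#' @param n_pcs Number of principal components kept; capped at the matrix
#'   rank.
#' @return A `feature_matrix`: list with `values` (N x n_pcs scores) and
#'   `feature_names`.
#' @export
preprocess_features <- function(counts, n_top_genes = 3000, n_pcs = 50) {
  counts <- as.matrix(counts)
  depth <- rowSums(counts)
  if (any(depth == 0)) stop("spots with zero total counts are not supported")
  x <- counts / depth * stats::median(depth)
  x <- log1p(x)
  v <- apply(x, 2L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, ncol(x)))]
  x <- x[, keep, drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  # PCA via the Gram-matrix route: cheap when genes far outnumber spots
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  scores <- e$vectors[, seq_len(n_pcs), drop = FALSE] *
    rep(sqrt(pmax(e$values[seq_len(n_pcs)], 0)), each = nrow(x))
  # deterministic sign: largest-magnitude coordinate of each PC positive
  for (j in seq_len(ncol(scores))) {
    i0 <- which.max(abs(scores[, j]))
    if (scores[i0, j] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(values = scores,
                 feature_names = paste0("PC", seq_len(n_pcs))),
            class = "feature_matrix")
}

activation_fun <- function(name) {
  switch(name,
         linear = identity,
         relu = function(x) pmax(x, 0),
         stop("unknown activation: ", name))
}

#' One graph-convolution layer
#'
#' Applies the layer-wise propagation rule Z_out = sigma(A Z W): the
#' normalized adjacency aggregates each spot's neighbourhood, an optional
#' weight matrix mixes channels, and an activation is applied. With
#' `weights = NULL` and linear activation this is pure message passing
#' A Z; a row-stochastic A then maps constant columns to themselves.
#'
#' @param z N x d matrix of node representations.
#' @param adjacency A `dw_adjacency` (either kind).
#' @param weights d x d' weight matrix, or `NULL` for identity.
#' @param activation `"linear"` or `"relu"`.
#' @return The propagated N x d' matrix.
#' @export
gcn_layer <- function(z, adjacency, weights = NULL,
                      activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  stopifnot(inherits(adjacency, "dw_adjacency"))
  z <- as.matrix(z)
  if (nrow(z) != nrow(adjacency$matrix))
    stop("adjacency is ", nrow(adjacency$matrix), " x ", ncol(adjacency$matrix),
         " but features have ", nrow(z), " rows")
  out <- as.matrix(adjacency$matrix %*% z)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (nrow(weights) != ncol(out))
      stop("weight matrix rows (", nrow(weights),
           ") must match feature columns (", ncol(out), ")")
    out <- out %*% weights
  }
  activation_fun(activation)(out)
}

#' Pipeline configuration
#'
#' @param k,p Graph parameters (neighbourhood size and distance-decay
#'   exponent) for the distance-weighted arm; the baseline arm uses the
#'   same `k`.
#' @param n_layers Number of propagation layers L (>= 1).
#' @param hidden_dims Embedding dimensionality.
#' @param activation `"linear"` or `"relu"`.
#' @param mode `"parameter_free"` (propagate, then truncated-SVD
#'   projection; no trained weights) or `"autoencoder"` (two-layer GCN
#'   encoder trained to reconstruct the features).
#' @param n_clusters Number of clusters C (>= 2).
#' @param n_runs Number of repeated runs R per arm.
#' @param seed Base seed; run r uses seed + r - 1.
#' @param epochs,learning_rate Autoencoder-mode training parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 12, p = 2, n_layers = 2, hidden_dims = 20,
                            activation = NULL,
                            mode = c("parameter_free", "autoencoder"),
                            n_clusters = 2, n_runs = 1, seed = 1L,
                            epochs = 100, learning_rate = 1e-3) {
  mode <- match.arg(mode)
  if (is.null(activation))
    activation <- if (mode == "parameter_free") "linear" else "relu"
  stopifnot(n_layers >= 1, n_clusters >= 2, n_runs >= 1, hidden_dims >= 1)
  structure(list(k = k, p = p, n_layers = as.integer(n_layers),
                 hidden_dims = as.integer(hidden_dims),
                 activation = activation, mode = mode,
                 n_clusters = as.integer(n_clusters),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 epochs = as.integer(epochs), learning_rate = learning_rate),
            class = "pipeline_config")
}

truncated_svd_project <- function(z, d) {
  d <- min(d, ncol(z), nrow(z))
  s <- svd(z, nu = d, nv = 0)
  scores <- s$u * rep(s$d[seq_len(d)], each = nrow(z))
  for (j in seq_len(ncol(scores))) {
    i0 <- which.max(abs(scores[, j]))
    if (scores[i0, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Embed features by graph propagation
#'
#' `parameter_free` mode applies the adjacency L times (linear message
#' passing, no trained weights) and projects to `hidden_dims` by truncated
#' SVD; it is fully deterministic and isolates the effect of the adjacency.
#' `autoencoder` mode trains a two-layer GCN encoder with a linear decoder
#' to reconstruct the features (full-batch Adam) and returns the encoder
#' output, demonstrating the propagation rule with learnable weights.
#'
#' @param features A `feature_matrix` from [preprocess_features()] (or a
#'   plain numeric matrix).
#' @param adjacency A `dw_adjacency`.
#' @param config A [pipeline_config()].
#' @return A `layer_state`: list with `z` (N x hidden_dims embedding),
#'   `layer_index`, and (autoencoder mode) `final_loss` and `converged`.
#' @export
embed <- function(features, adjacency, config) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (config$mode == "parameter_free") {
    act <- config$activation
    z <- x
    for (l in seq_len(config$n_layers))
      z <- gcn_layer(z, adjacency, weights = NULL, activation = act)
    z <- truncated_svd_project(z, config$hidden_dims)
    structure(list(z = z, layer_index = config$n_layers),
              class = "layer_state")
  } else {
    train_gcn_autoencoder(x, adjacency, config)
  }
}

# Two-layer GCN encoder (relu, linear) + linear decoder, squared
# reconstruction loss, full-batch Adam. Small and CPU-sized on purpose.
train_gcn_autoencoder <- function(x, adjacency, config) {
  set.seed(config$seed)
  a <- adjacency$matrix
  n <- nrow(x); m <- ncol(x)
  h1 <- max(config$hidden_dims * 2L, config$hidden_dims + 1L)
  h2 <- config$hidden_dims
  init <- function(p, q) matrix(stats::rnorm(p * q, sd = sqrt(2 / (p + q))), p, q)
  w <- list(init(m, h1), init(h1, h2), init(h2, m))
  mo <- lapply(w, function(wi) wi * 0); vo <- mo
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  loss0 <- NA_real_; loss <- NA_real_
  for (it in seq_len(config$epochs)) {
    ax <- as.matrix(a %*% x)
    h  <- pmax(ax %*% w[[1]], 0)            # encoder layer 1 (relu)
    az <- as.matrix(a %*% h)
    z  <- az %*% w[[2]]                     # encoder layer 2 (linear)
    xh <- z %*% w[[3]]                      # decoder
    r  <- xh - x
    loss <- mean(r^2)
    if (it == 1L) loss0 <- loss
    g3 <- crossprod(z, r) * (2 / length(r))
    gz <- r %*% t(w[[3]]) * (2 / length(r))
    g2 <- crossprod(az, gz)
    gh <- as.matrix(Matrix::t(a) %*% (gz %*% t(w[[2]])))
    gh <- gh * (h > 0)
    g1 <- crossprod(ax, gh)
    gr <- list(g1, g2, g3)
    for (j in 1:3) {
      mo[[j]] <- b1 * mo[[j]] + (1 - b1) * gr[[j]]
      vo[[j]] <- b2 * vo[[j]] + (1 - b2) * gr[[j]]^2
      w[[j]] <- w[[j]] - lr * (mo[[j]] / (1 - b1^it)) /
        (sqrt(vo[[j]] / (1 - b2^it)) + eps)
    }
  }
  converged <- is.finite(loss) && loss < loss0
  if (!converged)
    warning("autoencoder did not reduce the reconstruction loss (final loss ",
            signif(loss, 6), ", initial ", signif(loss0, 6), ")")
  ax <- as.matrix(a %*% x)
  h  <- pmax(ax %*% w[[1]], 0)
  z  <- as.matrix(a %*% h) %*% w[[2]]
  structure(list(z = z, layer_index = 2L, final_loss = loss,
                 converged = converged),
            class = "layer_state")
}

#' Cluster an embedding
#'
#' K-means head with multiple restarts and a fixed seed. Label identity is
#' arbitrary (all downstream metrics are permutation-invariant), but a
#' given (embedding, C, seed) always returns identical labels.
#'
#' @param embedding A `layer_state` (or plain matrix).
#' @param n_clusters Number of clusters C (<= N).
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts.
#' @return Integer vector of labels in 1..C.
#' @export
cluster_embedding <- function(embedding, n_clusters, seed = 1L, nstart = 10) {
  z <- if (inherits(embedding, "layer_state")) embedding$z else as.matrix(embedding)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > nrow(z))
    stop("n_clusters (", n_clusters, ") exceeds the number of spots (", nrow(z), ")")
  set.seed(seed)
  if (n_clusters == nrow(z)) return(seq_len(nrow(z)))
  km <- stats::kmeans(z, centers = n_clusters, nstart = nstart,
                      iter.max = 100)
  as.integer(km$cluster)
}

#' Run the reference pipeline on one dataset
#'
#' Builds the requested adjacency once (deterministic), preprocesses the
#' counts, embeds, and runs the clustering head R times with run-specific
#' seeds `seed + 0 .. seed + R - 1`. This is the per-arm unit of the paired
#' benchmarking design: calling it twice on the same dataset with
#' `adjacency_kind = "baseline"` and `"dw"` yields two aligned R-run label
#' collections.
#'
#' @param dataset A `simulated_dataset` (or any list with `spots`, `counts`
#'   and `truth$n_domains`).
#' @param config A [pipeline_config()]; `n_clusters` defaults to the
#'   dataset's ground-truth domain count when available.
#' @param adjacency_kind `"dw"` (row-normalized inverse-distance weights)
#'   or `"baseline"` (symmetric degree normalization).
#' @return A list with `labels` (N x R integer matrix, one column per run),
#'   `embedding`, `adjacency_kind`, and `config`.
#' @export
run_pipeline <- function(dataset, config, adjacency_kind = c("dw", "baseline")) {
  adjacency_kind <- match.arg(adjacency_kind)
  stopifnot(inherits(config, "pipeline_config"))
  adj <- if (adjacency_kind == "dw")
    build_dw_adjacency(dataset$spots, k = config$k, p = config$p)
  else
    build_baseline_adjacency(dataset$spots, k = config$k)
  feats <- preprocess_features(dataset$counts)
  c_use <- config$n_clusters
  if (!is.null(dataset$truth)) c_use <- dataset$truth$n_domains
  emb <- embed(feats, adj, config)
  labels <- vapply(seq_len(config$n_runs) - 1L, function(r) {
    if (config$mode == "autoencoder" && r > 0L) {
      cfg_r <- config
      cfg_r$seed <- config$seed + r        # run-specific training seed
      emb_r <- embed(feats, adj, cfg_r)
      cluster_embedding(emb_r, c_use, seed = config$seed + r)
    } else {
      cluster_embedding(emb, c_use, seed = config$seed + r)
    }
  }, integer(nrow(emb$z)))
  labels <- matrix(labels, ncol = config$n_runs)
  list(labels = labels, embedding = emb, adjacency_kind = adjacency_kind,
       config = config)
}
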