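#' Lattice specification
#'
#' Describes the spot geometry of a synthetic section. Hexagonal lattices
#' mirror Visium-style arrays (offset rows, row pitch spacing * sqrt(3)/2,
#' six equidistant nearest neighbours at interior nodes); square lattices
#' and uniform random point clouds are available for fixtures.
#'
#' @param geometry One of `"hexagonal"`, `"square"`, `"uniform_random"`.
#' @param n_rows,n_cols Lattice dimensions (ignored for `uniform_random`).
#' @param n_points Number of points for `uniform_random`.
#' @param spacing Positive spot pitch in arbitrary length units.
#' @param jitter_sd Gaussian positional noise, as a fraction of `spacing`.
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(geometry = c("hexagonal", "square", "uniform_random"),
                         n_rows = 30, n_cols = 30, n_points = NULL,
                         spacing = 1, jitter_sd = 0) {
  geometry <- match.arg(geometry)
  stopifnot(spacing > 0, jitter_sd >= 0)
  if (geometry == "uniform_random") {
    if (is.null(n_points)) n_points <- n_rows * n_cols
    stopifnot(n_points >= 2)
  } else {
    stopifnot(n_rows >= 1, n_cols >= 1, n_rows * n_cols >= 2)
  }
  structure(list(geometry = geometry, n_rows = n_rows, n_cols = n_cols,
                 n_points = n_points, spacing = spacing,
                 jitter_sd = jitter_sd),
            class = "lattice_spec")
}

#' Generate spot coordinates from a lattice specification
#'
#' @param spec A [lattice_spec()].
#' @param seed Integer seed; only consulted when the spec involves
#'   randomness (jitter or uniform_random placement).
#' @return A [spot_table].
#' @examples
#' st <- make_lattice(lattice_spec("hexagonal", n_rows = 10, n_cols = 10))
#' n_spots(st)  # 100
#' @export
make_lattice <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lattice_spec"))
  s <- spec$spacing
  if (spec$geometry == "uniform_random") {
    set.seed(seed)
    n <- spec$n_points
    coords <- cbind(stats::runif(n, 0, sqrt(n) * s),
                    stats::runif(n, 0, sqrt(n) * s))
  } else {
    g <- expand.grid(col = seq_len(spec$n_cols) - 1L,
                     row = seq_len(spec$n_rows) - 1L)
    x <- g$col * s
    y <- g$row * s
    if (spec$geometry == "hexagonal") {
      x <- x + (g$row %% 2L) * s / 2   # offset every other row
      y <- g$row * s * sqrt(3) / 2
    }
    coords <- cbind(x, y)
  }
  if (spec$jitter_sd > 0) {
    set.seed(seed + 1L)
    coords <- coords +
      matrix(stats::rnorm(length(coords), sd = spec$jitter_sd * s),
             ncol = 2L)
  }
  spot_table(sprintf("spot_%05d", seq_len(nrow(coords))), coords)
}

#' Partition spots into spatially contiguous domains
#'
#' Assigns each spot one of D ground-truth domain labels following a
#' spatial pattern: `"voronoi"` draws D seed spots and labels every spot by
#' its nearest seed (irregular but contiguous domains, the default used in
#' the simulation scenarios); `"stripes"` cuts D equal-width vertical
#' bands; `"nested_rings"` cuts D concentric annuli around the centroid
#' with equal spot counts per ring.
#'
#' @param spots A [spot_table].
#' @param n_domains Number of domains D (2 <= D <= N).
#' @param pattern One of `"voronoi"`, `"stripes"`, `"nested_rings"`.
#' @param seed Integer seed for the Voronoi seed draw.
#' @return A `domain_map`: list with integer `labels` in 1..D (all D
#'   present), `n_domains`, and `pattern`.
#' @export
make_domains <- function(spots, n_domains,
                         pattern = c("voronoi", "stripes", "nested_rings"),
                         seed = 1L) {
  stopifnot(inherits(spots, "spot_table"))
  pattern <- match.arg(pattern)
  n <- n_spots(spots)
  d <- as.integer(n_domains)
  stopifnot(d >= 1L, d <= n)
  labels <- switch(pattern,
    voronoi = {
      set.seed(seed)
      lab <- NULL
      for (try in seq_len(100L)) {
        centers <- spots$coords[sample.int(n, d), , drop = FALSE]
        dd <- outer(rowSums(spots$coords^2), rowSums(centers^2), "+") -
          2 * spots$coords %*% t(centers)
        cand <- max.col(-dd, ties.method = "first")
        if (length(unique(cand)) == d) { lab <- cand; break }
      }
      if (is.null(lab)) stop("could not draw ", d, " nonempty Voronoi domains")
      lab
    },
    stripes = {
      br <- stats::quantile(spots$coords[, 1], probs = seq(0, 1, length.out = d + 1))
      lab <- findInterval(spots$coords[, 1], br[-c(1, d + 1)]) + 1L
      if (length(unique(lab)) != d) stop("degenerate stripe partition")
      lab
    },
    nested_rings = {
      ctr <- colMeans(spots$coords)
      r <- sqrt(colSums((t(spots$coords) - ctr)^2))
      lab <- as.integer(cut(rank(r, ties.method = "first"),
                            breaks = d, labels = FALSE))
      lab
    })
  structure(list(labels = as.integer(labels), n_domains = d, pattern = pattern),
            class = "domain_map")
}

#' Negative-binomial expression model
#'
#' Parameterizes domain-specific counts. Gene g in spot i of domain d is
#' drawn NB with mean `mu_g * F_{g,d} * lambda_i` and dispersion `theta`
#' (variance mu + mu^2 / theta), where F is `fold_change` on that domain's
#' marker genes and 1 elsewhere, and lambda_i is a log-normal library-size
#' factor with log-sd `libsize_sd`. Baseline gene means mu_g are drawn
#' log-normal around `base_mean`. Each domain gets its own disjoint marker
#' set of `round(marker_fraction * n_genes)` genes.
#'
#' @param n_genes Number of genes M.
#' @param marker_fraction Fraction of genes elevated per domain (the marker
#'   sets of different domains are disjoint; D * marker_fraction must be
#'   below 1).
#' @param fold_change Multiplicative elevation of a domain's markers.
#' @param dispersion NB dispersion theta (> 0); larger is closer to Poisson.
#' @param libsize_sd Log-normal sd of per-spot library-size factors.
#' @param base_mean Median baseline mean count per gene.
#' @return An `expression_model` list.
#' @export
expression_model <- function(n_genes = 2000, marker_fraction = 0.05,
                             fold_change = 3, dispersion = 2,
                             libsize_sd = 0.2, base_mean = 1) {
  stopifnot(n_genes >= 1, marker_fraction > 0, marker_fraction < 1,
            fold_change > 0, dispersion > 0, libsize_sd >= 0, base_mean > 0)
  structure(list(n_genes = as.integer(n_genes),
                 marker_fraction = marker_fraction,
                 fold_change = fold_change, dispersion = dispersion,
                 libsize_sd = libsize_sd, base_mean = base_mean),
            class = "expression_model")
}

#' Simulate counts for a labelled section
#'
#' @param spots A [spot_table].
#' @param truth A `domain_map` from [make_domains()].
#' @param model An [expression_model()].
#' @param seed Integer seed; the draw is bit-reproducible.
#' @return A `simulated_dataset`: list with `spots`, `counts` (N x M
#'   integer matrix, genes in columns), `truth`, `model`, and `seed`.
#' @export
simulate_counts <- function(spots, truth, model, seed = 1L) {
  stopifnot(inherits(spots, "spot_table"), inherits(truth, "domain_map"),
            inherits(model, "expression_model"))
  n <- n_spots(spots)
  stopifnot(length(truth$labels) == n)
  m <- model$n_genes
  d <- truth$n_domains
  n_mark <- round(model$marker_fraction * m)
  if (d * n_mark > m)
    stop("marker sets exhaust the gene pool: ", d, " domains x ", n_mark,
         " markers > ", m, " genes")
  set.seed(seed)
  mu <- model$base_mean * exp(stats::rnorm(m, 0, 0.5))  # gene baselines
  # disjoint marker blocks, one per domain
  marker_of <- rep.int(0L, m)
  if (n_mark > 0)
    marker_of[seq_len(d * n_mark)] <- rep(seq_len(d), each = n_mark)
  lambda <- exp(stats::rnorm(n, 0, model$libsize_sd))
  # mean matrix: mu_g * fold on (spot in domain d, gene marker of d)
  mean_mat <- matrix(mu, n, m, byrow = TRUE) * lambda
  if (n_mark > 0) {
    idx <- which(outer(truth$labels, marker_of, "=="))
    mean_mat[idx] <- mean_mat[idx] * model$fold_change
  }
  counts <- matrix(stats::rnbinom(n * m, mu = mean_mat, size = model$dispersion),
                   n, m)
  dimnames(counts) <- list(spots$spot_id, sprintf("gene_%05d", seq_len(m)))
  structure(list(spots = spots, counts = counts, truth = truth,
                 model = model, seed = seed),
            class = "simulated_dataset")
}

derive_seed <- function(base_seed, index) {
  # splittable counter: distinct, decorrelated streams per replicate,
  # kept within 32-bit integer range
  as.integer((as.numeric(base_seed) * 7919 + index * 104729) %% 2147483629)
}

#' Generate a multi-replicate simulation scenario
#'
#' Builds the `cluster_3` / `cluster_5` / `cluster_8` / `cluster_10`
#' scenarios: tissues with 3, 5, 8 or 10 spatially contiguous domains on a
#' shared lattice and expression model, with `n_replicates` independently
#' generated samples per scenario (independent domain draws and counts,
#' derived seeds).
#'
#' @param scenario One of `"cluster_3"`, `"cluster_5"`, `"cluster_8"`,
#'   `"cluster_10"`.
#' @param n_replicates Number of independent samples (default 8).
#' @param base_seed Integer base seed; replicate r uses a seed derived from
#'   `(base_seed, r)` via a splittable counter.
#' @param spec Lattice specification shared by all replicates (default
#'   30 x 30 hexagonal).
#' @param model Expression model shared by all replicates.
#' @param pattern Domain pattern (default `"voronoi"`).
#' @return A list of `n_replicates` `simulated_dataset` objects, each
#'   carrying `scenario_id` and `replicate_index`.
#' @export
make_scenario <- function(scenario = c("cluster_3", "cluster_5", "cluster_8",
                                       "cluster_10"),
                          n_replicates = 8, base_seed = 1L,
                          spec = lattice_spec("hexagonal", 30, 30),
                          model = expression_model(),
                          pattern = "voronoi") {
  scenario <- match.arg(scenario)
  d <- as.integer(sub("cluster_", "", scenario))
  spots <- make_lattice(spec, seed = derive_seed(base_seed, 0L))
  lapply(seq_len(n_replicates), function(r) {
    sd_r <- derive_seed(base_seed, r)
    truth <- make_domains(spots, d, pattern = pattern, seed = sd_r)
    ds <- simulate_counts(spots, truth, model, seed = sd_r + 1L)
    ds$scenario_id <- scenario
    ds$replicate_index <- r
    ds
  })
}
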