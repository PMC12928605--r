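# Independent brute-force oracles. Everything here is deliberately naive
# (explicit loops, dense matrices) and shares no code with the package.

oracle_pairwise_dist <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  d
}

oracle_dw_adjacency <- function(coords, k, p) {
  n <- nrow(coords)
  d0 <- oracle_pairwise_dist(coords)
  nn <- numeric(n)
  for (i in seq_len(n)) nn[i] <- min(d0[i, -i])
  drel <- 1 + d0 / mean(nn)
  diag(drel) <- 1
  k <- min(k, n - 1)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d0[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    w[i, ord] <- drel[i, ord]^(-p)
    w[i, i] <- 1
  }
  sweep(w, 1, rowSums(w), "/")
}

oracle_baseline_adjacency <- function(coords, k) {
  n <- nrow(coords)
  d0 <- oracle_pairwise_dist(coords)
  k <- min(k, n - 1)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d0[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    a[i, ord] <- 1
  }
  a <- pmax(a, t(a))          # union symmetrization
  diag(a) <- 1                # self-loops
  d <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (a[i, j] > 0) out[i, j] <- 1 / sqrt(d[i] * d[j])
  out
}

# Pair-counting ARI (Hubert-Arabie) by exhaustive enumeration of pairs.
oracle_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- truth[i] == truth[j]
      sp <- pred[i] == pred[j]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)   # both partitions trivial in the same way
  2 * (a * d - b * cc) / den
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_nmi <- function(truth, pred) {
  n <- length(truth)
  ht <- oracle_entropy(truth)
  hp <- oracle_entropy(pred)
  if (ht == 0 && hp == 0) return(1)
  mi <- 0
  for (t in unique(truth)) {
    for (q in unique(pred)) {
      pij <- sum(truth == t & pred == q) / n
      if (pij > 0)
        mi <- mi + pij * log(pij / (sum(truth == t) / n * sum(pred == q) / n))
    }
  }
  mi / ((ht + hp) / 2)
}

oracle_homogeneity <- function(truth, pred) {
  ht <- oracle_entropy(truth)
  if (ht == 0) return(1)
  hcond <- 0
  for (q in unique(pred)) {
    sel <- pred == q
    hcond <- hcond + sum(sel) / length(pred) * oracle_entropy(truth[sel])
  }
  1 - hcond / ht
}

# Exact two-sided signed-rank p by full 2^n sign enumeration (no ties).
oracle_wilcoxon_exact <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Step-up BH by the textbook definition: adj_(i) = min_{j >= i} p_(j) n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[ord] <- adj
  out
}

oracle_cliffs <- function(x, y) {
  gt <- lt <- 0
  for (xi in x) for (yi in y) {
    if (xi > yi) gt <- gt + 1
    if (xi < yi) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

random_spots <- function(n, seed) {
  set.seed(seed)
  spot_table(sprintf("s%03d", seq_len(n)),
             cbind(runif(n, 0, 10), runif(n, 0, 10)))
}

# Central (most interior) node of a spot table.
central_spot <- function(spots) {
  which.min(colSums((t(spots$coords) - colMeans(spots$coords))^2))
}
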