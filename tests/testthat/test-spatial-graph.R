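test_that("relative distances follow the mean nearest-neighbour scaling", {
  st <- spot_table(c("a", "b"), cbind(c(0, 0), c(0, 1)))
  rd <- compute_relative_distances(st)
  expect_equal(rd$d_bar_min, 1)
  expect_equal(rd$d_rel, matrix(c(1, 2, 2, 1), 2), tolerance = 1e-12)

  # collinear triple: d_bar_min = (1 + 1 + 2)/3 = 4/3
  st3 <- spot_table(letters[1:3], cbind(c(0, 1, 3), 0))
  rd3 <- compute_relative_distances(st3)
  expect_equal(rd3$d_bar_min, 4 / 3)
  expect_equal(rd3$d_rel[1, 2], 1.75)
  expect_equal(rd3$d_rel[2, 3], 2.5)
  expect_equal(rd3$d_rel[1, 3], 3.25)

  # unit diagonal, symmetry, off-diagonal > 1 on random point sets
  for (seed in 1:3) {
    st <- random_spots(30, seed)
    rd <- compute_relative_distances(st)
    expect_equal(diag(rd$d_rel), rep(1, 30))
    expect_equal(rd$d_rel, t(rd$d_rel), tolerance = 1e-12)
    expect_true(all(rd$d_rel[upper.tri(rd$d_rel)] > 1))
  }
})

test_that("duplicate coordinates are an error unless jitter is requested", {
  st <- spot_table(c("a", "b", "c"), cbind(c(0, 0, 1), c(0, 0, 0)))
  expect_error(compute_relative_distances(st), "duplicate")
  set.seed(1)
  rd <- compute_relative_distances(st, on_duplicates = "jitter")
  expect_true(all(rd$d_rel[upper.tri(rd$d_rel)] > 1))
})

test_that("KNN graph is asymmetric, ordered, and index-tie-broken", {
  # collinear: spot 3's edge to 2 is not reciprocated
  st3 <- spot_table(letters[1:3], cbind(c(0, 1, 3), 0))
  g <- build_knn_graph(st3, 1)
  expect_identical(g$neighbor_lists, list(2L, 1L, 2L))
  expect_true(g$include_self)

  # saturated: k >= N-1 returns all other spots (with a warning past N-1)
  expect_warning(gs <- build_knn_graph(st3, 5), "truncating")
  expect_identical(lapply(gs$neighbor_lists, sort),
                   list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))

  # square-lattice interior node, k = 4: the four axis-adjacent nodes
  st <- make_lattice(lattice_spec("square", 7, 7))
  ctr <- central_spot(st)
  g4 <- build_knn_graph(st, 4)
  expect_setequal(g4$neighbor_lists[[ctr]],
                  c(ctr - 1L, ctr + 1L, ctr - 7L, ctr + 7L))

  # exact distance ties broken by ascending spot index
  stx <- spot_table(letters[1:4], cbind(c(0, 1, -1, 0), c(0, 0, 0, 1)))
  gt <- build_knn_graph(stx, 1)
  expect_identical(gt$neighbor_lists[[1]], 2L)

  # no spot is its own neighbour; list lengths equal min(k, N-1)
  st <- random_spots(40, seed = 11)
  g6 <- build_knn_graph(st, 6)
  for (i in seq_len(40)) {
    expect_false(i %in% g6$neighbor_lists[[i]])
    expect_length(g6$neighbor_lists[[i]], 6L)
  }

  expect_error(build_knn_graph(st, 0), "positive")
})

test_that("IDW weights follow d_rel^(-p) with unit self-loops", {
  st <- random_spots(20, seed = 3)
  rd <- compute_relative_distances(st)
  g <- build_knn_graph(st, 5)

  w0 <- idw_weights(g, rd, 0)
  expect_true(all(w0$matrix@x == 1))                 # x^0 = 1 everywhere
  expect_equal(Matrix::rowSums(w0$matrix != 0), rep(6, 20),
               ignore_attr = TRUE)                   # k + 1 nonzeros per row

  w2 <- idw_weights(g, rd, 2)
  expect_equal(unname(Matrix::diag(w2$matrix)), rep(1, 20))  # self-loop 1 for all p
  j <- g$neighbor_lists[[1]][1]
  expect_equal(w2$matrix[1, j], rd$d_rel[1, j]^-2)
  # an edge at relative distance 2 with p = 2 weighs exactly 1/4
  st2 <- spot_table(c("a", "b"), cbind(c(0, 0), c(0, 1)))
  w <- idw_weights(build_knn_graph(st2, 1), compute_relative_distances(st2), 2)
  expect_equal(w$matrix[1, 2], 0.25)

  expect_error(idw_weights(g, rd, -1), "non-negative")
})

test_that("row normalization yields row-stochastic matrices, pattern intact", {
  st <- random_spots(30, seed = 5)
  raw <- idw_weights(build_knn_graph(st, 12), compute_relative_distances(st), 2)
  norm <- row_normalize(raw)
  expect_equal(Matrix::rowSums(norm$matrix), rep(1, 30),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(as.matrix(norm$matrix != 0), as.matrix(raw$matrix != 0))
  # relative within-row ordering preserved
  r1 <- as.numeric(raw$matrix[1, ]); n1 <- as.numeric(norm$matrix[1, ])
  expect_identical(order(r1), order(n1))
  expect_error(row_normalize(norm), "raw_idw")
})

test_that("hexagonal interior weight profile matches the analytic values", {
  # ideal geometry: 6 neighbours at d_rel = 2, 6 at d_rel = 1 + sqrt(3)
  st <- make_lattice(lattice_spec("hexagonal", 15, 15))
  ctr <- central_spot(st)
  a <- build_dw_adjacency(st, k = 12, p = 2)
  s <- 1 + 6 / 4 + 6 * (1 + sqrt(3))^-2
  expect_equal(a$matrix[ctr, ctr], 1 / s, tolerance = 1e-9)          # ~0.3027
  row <- as.numeric(a$matrix[ctr, ])
  vals <- sort(unique(round(row[row > 0], 9)), decreasing = TRUE)
  expect_equal(vals, c(1, 0.25, (1 + sqrt(3))^-2) / s, tolerance = 1e-6)
  # uniform limit: p = 0 gives 13 equal entries of 1/13
  a0 <- build_dw_adjacency(st, k = 12, p = 0)
  expect_equal(as.numeric(a0$matrix[ctr, a0$matrix[ctr, ] > 0]),
               rep(1 / 13, 13))
})

test_that("dw adjacency properties hold across k, p, and geometry", {
  for (seed in 1:4) {
    st <- random_spots(35, seed = 100 + seed)
    k <- c(4, 6, 12, 8)[seed]
    for (p in c(0, 0.5, 2, 4)) {
      a <- build_dw_adjacency(st, k = k, p = p)
      m <- a$matrix
      expect_equal(Matrix::rowSums(m), rep(1, 35), tolerance = 1e-9,
                   ignore_attr = TRUE)
      dg <- Matrix::diag(m)
      for (i in seq_len(35)) {
        ri <- as.numeric(m[i, ])
        off <- ri[-i][ri[-i] > 0]
        if (p > 0) expect_gt(dg[i], max(off))          # strict self dominance
        else expect_equal(max(abs(off - dg[i])), 0)    # ties at p = 0
      }
    }
  }
})

test_that("within-row weights decay monotonically with relative distance", {
  st <- random_spots(40, seed = 9)
  rd <- compute_relative_distances(st)
  a <- build_dw_adjacency(st, k = 8, p = 2)
  for (i in c(1, 10, 25, 40)) {
    ri <- as.numeric(a$matrix[i, ])
    idx <- which(ri > 0)
    ord <- idx[order(rd$d_rel[i, idx])]
    expect_true(all(diff(ri[ord]) <= 1e-15))
  }
})

test_that("self-weight is monotone in p and saturates for large p", {
  st <- make_lattice(lattice_spec("hexagonal", 15, 15))
  ctr <- central_spot(st)
  selfs <- vapply(c(0, 0.5, 1, 2, 4, 8),
                  function(p) build_dw_adjacency(st, 12, p)$matrix[ctr, ctr],
                  numeric(1))
  expect_true(all(diff(selfs) > 0))
  expect_gte(selfs[length(selfs)], 0.97)   # p = 8 on the ideal lattice
})

test_that("dw adjacency is invariant to a global coordinate rescaling", {
  st <- random_spots(30, seed = 21)
  a1 <- build_dw_adjacency(st, k = 6, p = 2)
  for (c_scale in c(0.001, 7, 1e4)) {
    st2 <- spot_table(st$spot_id, st$coords * c_scale)
    a2 <- build_dw_adjacency(st2, k = 6, p = 2)
    expect_lt(max(abs(a1$matrix - a2$matrix)), 1e-12)
  }
})

test_that("graph construction matches the dense brute-force oracle", {
  st <- random_spots(50, seed = 33)
  a <- build_dw_adjacency(st, k = 6, p = 2)
  expect_lt(max(abs(as.matrix(a$matrix) - oracle_dw_adjacency(st$coords, 6, 2))),
            1e-12)
  b <- build_baseline_adjacency(st, k = 6)
  expect_lt(max(abs(as.matrix(b$matrix) - oracle_baseline_adjacency(st$coords, 6))),
            1e-12)
})

test_that("baseline adjacency is symmetric with 1/sqrt(d_i d_j) entries", {
  # fully connected pair: A = [[1,1],[1,1]], D = diag(2,2), entries 1/2
  st2 <- spot_table(c("a", "b"), cbind(c(0, 0), c(0, 1)))
  b2 <- build_baseline_adjacency(st2, k = 1)
  expect_equal(as.matrix(b2$matrix), matrix(0.5, 2, 2), ignore_attr = TRUE)

  st <- random_spots(50, seed = 13)
  b <- build_baseline_adjacency(st, k = 6)
  m <- as.matrix(b$matrix)
  expect_identical(m, t(m))                         # exact symmetry
  expect_true(all(m >= 0 & m <= 1))
  deg <- rowSums(m != 0)
  edges <- which(m != 0, arr.ind = TRUE)
  expect_equal(m[edges], 1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # interior of a large regular lattice, k = 12: mutual KNN, self-loop 1/13
  sth <- make_lattice(lattice_spec("hexagonal", 15, 15))
  ctr <- central_spot(sth)
  bh <- build_baseline_adjacency(sth, k = 12)
  expect_equal(bh$matrix[ctr, ctr], 1 / 13, tolerance = 1e-12)
})
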