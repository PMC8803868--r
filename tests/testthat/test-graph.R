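# Column-correlation graphs, Louvain modules, the four weighted metrics
# against brute-force oracles, null models and feature assembly.

test_that("correlation graphs clip negatives and zero constant columns", {
  g <- mean_geometry()
  amp <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1), c(5, 5, 5, 5))
  m <- connectivity_map(amp, 20, c(-30, -10, 10, 30), g)
  gr <- build_correlation_graph(m)
  expect_equal(gr$adjacency[1, 2], 1)            # identical direction
  expect_equal(gr$adjacency[1, 3], 0)            # anticorrelated, clipped
  expect_true(all(gr$adjacency[, 4] == 0))       # constant column
  expect_equal(diag(gr$adjacency), rep(0, 4))
  expect_true(isSymmetric(gr$adjacency))
  expect_error(build_correlation_graph(
    connectivity_map(matrix(1:2, 2, 1), 20, 0, g)), "2 columns")
})

test_that("correlation graphs match an element-wise oracle and are affine invariant", {
  set.seed(41)
  amp <- matrix(runif(6 * 16, 0, 80), 6, 16)
  m <- toy_map(amp)
  gr <- build_correlation_graph(m)
  for (x in seq_len(16)) for (xp in seq_len(16)) {
    expected <- if (x == xp) 0 else max(cor(amp[, x], amp[, xp]), 0)
    expect_equal(gr$adjacency[x, xp], expected, tolerance = 1e-12)
  }
  m2 <- toy_map(2.5 * amp + 7)
  expect_equal(build_correlation_graph(m2)$adjacency, gr$adjacency,
               tolerance = 1e-12)
})

test_that("module detection separates disconnected cliques deterministically", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  gr <- map_graph(W)
  p <- detect_modules(gr, seed = 2)
  expect_equal(p$n_modules, 2L)
  expect_equal(p$membership, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(detect_modules(gr, seed = 2), detect_modules(gr, seed = 2))
  # empty graph: single trivial module
  p0 <- detect_modules(map_graph(matrix(0, 4, 4)), seed = 1)
  expect_equal(p0$membership, rep(1L, 4))
})

test_that("louvain modularity attains the exhaustive maximum on small graphs", {
  set.seed(43)
  for (k in 1:5) {
    n <- sample(5:8, 1)
    W <- random_weighted_graph(n, density = 0.6)
    if (sum(W) == 0) next
    gr <- map_graph(W)
    p <- detect_modules(gr, seed = 10 + k)
    expect_equal(p$modularity, oracle_best_modularity(W), tolerance = 1e-9)
  }
})

test_that("modularity evaluates the weighted quality function exactly", {
  # two disjoint dyads, 2-module partition: Q = 0.5 by direct evaluation
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  gr <- map_graph(W)
  expect_equal(graph_modularity(gr, c(1, 1, 2, 2)), 0.5)
  expect_equal(oracle_modularity(W, c(1, 1, 2, 2)), 0.5)
  # random graphs and partitions match the double-loop oracle
  set.seed(47)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    W <- random_weighted_graph(n)
    if (sum(W) == 0) next
    m <- sample(1:3, n, replace = TRUE)
    expect_equal(graph_modularity(map_graph(W), m), oracle_modularity(W, m),
                 tolerance = 1e-9)
  }
  # one-module partition of a complete graph, evaluated by oracle
  W <- matrix(1, 5, 5); diag(W) <- 0
  expect_equal(graph_modularity(map_graph(W), rep(1, 5)),
               oracle_modularity(W, rep(1, 5)), tolerance = 1e-12)
  expect_error(graph_modularity(map_graph(matrix(0, 3, 3)), rep(1, 3)),
               "zero total weight")
})

test_that("module degree z-scores standardise within modules", {
  # identical within-degrees: all zero by the sigma = 0 convention
  W <- matrix(1, 4, 4); diag(W) <- 0
  expect_equal(module_degree_zscore(map_graph(W), rep(1, 4)), rep(0, 4))
  # 3-node path inside one module: centre above, ends below
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  z <- module_degree_zscore(map_graph(W), rep(1, 3))
  expect_lt(z[1], 0); expect_gt(z[2], 0)
  expect_equal(z, oracle_module_degree_zscore(W, rep(1, 3)), tolerance = 1e-12)
  # per-module mean is zero wherever sigma > 0
  set.seed(53)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    W <- random_weighted_graph(n)
    m <- sample(1:3, n, replace = TRUE)
    z <- module_degree_zscore(map_graph(W), m)
    expect_equal(z, oracle_module_degree_zscore(W, m), tolerance = 1e-9)
    for (mod in unique(m)) {
      zm <- z[m == mod]
      if (any(zm != 0)) expect_equal(mean(zm), 0, tolerance = 1e-9)
    }
  }
})

test_that("participation measures cross-module weight spread", {
  # all links inside the own module
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_equal(participation(map_graph(W), c(1, 1, 2, 2)), rep(0, 4))
  # degree split equally between two modules: y = 0.5
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[1, 3] <- W[3, 1] <- 1
  y <- participation(map_graph(W), c(1, 1, 2))
  expect_equal(y[1], 0.5)
  # random graphs match the oracle; bound 1 - 1/|M|
  set.seed(59)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    W <- random_weighted_graph(n)
    m <- sample(1:3, n, replace = TRUE)
    y <- participation(map_graph(W), m)
    expect_equal(y, oracle_participation(W, m), tolerance = 1e-9)
    expect_true(all(y <= 1 - 1 / length(unique(m)) + 1e-12))
    expect_true(all(y >= 0))
  }
})

test_that("assortativity follows the weighted degree-correlation form", {
  # regular graph: 0/0, explicitly undefined
  W <- matrix(1, 4, 4); diag(W) <- 0
  expect_true(is.na(assortativity_weighted(map_graph(W))))
  # star graph: disassortative, matching the oracle
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 1
  r <- assortativity_weighted(map_graph(W))
  expect_lt(r, 0)
  expect_equal(r, oracle_assortativity(W), tolerance = 1e-12)
  # two disjoint copies have the same assortativity as one
  W2 <- matrix(0, 10, 10); W2[1:5, 1:5] <- W; W2[6:10, 6:10] <- W
  expect_equal(assortativity_weighted(map_graph(W2)), r, tolerance = 1e-12)
  # random graphs match the oracle
  set.seed(61)
  for (k in 1:20) {
    n <- sample(4:12, 1)
    W <- random_weighted_graph(n)
    got <- assortativity_weighted(map_graph(W))
    want <- oracle_assortativity(W)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("null rewiring preserves the degree sequence", {
  set.seed(67)
  W <- random_weighted_graph(12, density = 0.4)
  gr <- map_graph(W)
  nulls <- null_ensemble(gr, n_nulls = 5, seed = 3)
  deg0 <- rowSums(gr$adjacency > 0)
  w0 <- sort(gr$adjacency[upper.tri(gr$adjacency) & gr$adjacency > 0])
  moved <- FALSE
  for (nl in nulls) {
    expect_equal(rowSums(nl$adjacency > 0), deg0)
    expect_equal(sort(nl$adjacency[upper.tri(nl$adjacency) &
                                     nl$adjacency > 0]), w0)
    expect_true(isSymmetric(nl$adjacency))
    if (!identical(nl$adjacency, gr$adjacency)) moved <- TRUE
  }
  expect_true(moved)
  # reproducible given the seed
  expect_identical(null_ensemble(gr, n_nulls = 2, seed = 9),
                   null_ensemble(gr, n_nulls = 2, seed = 9))
  # single edge: nothing to swap
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 0.7
  expect_warning(n1 <- null_ensemble(map_graph(W1), n_nulls = 2, seed = 1),
                 "too few edges")
  expect_equal(n1[[1]]$adjacency, W1)
  expect_false(attr(n1[[1]], "rewired"))
})

test_that("relative metrics are percent deviations from the null median", {
  expect_equal(relative_metric(5, c(5, 5, 5)), 0)
  expect_equal(relative_metric(10, c(5, 5, 5)), 100)
  expect_equal(relative_metric(2.5, c(5, 5, 5)), -50)
  expect_true(is.na(relative_metric(3, c(0, 0, 0))))
  expect_error(relative_metric(3, c(NA, NaN)), "no finite null")
})

test_that("feature vectors have the published dimensions and symmetry", {
  set.seed(71)
  m <- toy_map(matrix(runif(96, 0, 60), 6, 16))
  gr <- build_correlation_graph(m)
  p <- detect_modules(gr, seed = 1)
  expect_length(assemble_features(gr, p, scheme = "g_global"), 4L)
  expect_length(assemble_features(gr, p, scheme = "g_bilateral"), 7L)
  zones <- structural_zones(m$positions, m$geometry, "bands8")
  zm <- compute_zscore_map(m, noise_mean = 6, noise_sd = 3)
  fw <- assemble_features(gr, p, scheme = "g_weights_zonewise",
                          zones = zones, map = m, zmap = zm)
  expect_length(fw, length(unique(as.character(zones))))
  expect_true(max(fw, na.rm = TRUE) <= 1)
  # a side-symmetric graph yields identical ipsi and contra entries
  Wl <- matrix(0, 4, 4)
  Wl[1, 2] <- Wl[2, 1] <- 0.8; Wl[3, 4] <- Wl[4, 3] <- 0.8
  Wl[2, 3] <- Wl[3, 2] <- 0.2
  gs <- map_graph(Wl, positions_um = c(-30, -10, 10, 30))
  ps <- detect_modules(gs, seed = 1)
  fb <- assemble_features(gs, ps, scheme = "g_bilateral")
  expect_equal(fb[["z_ipsi"]], fb[["z_contra"]])
  expect_equal(fb[["y_ipsi"]], fb[["y_contra"]])
})

test_that("relative and zone-wise feature schemes assemble correctly", {
  set.seed(73)
  m <- toy_map(matrix(runif(96, 0, 60), 6, 16))
  gr <- build_correlation_graph(m)
  p <- detect_modules(gr, seed = 1)
  nulls <- null_ensemble(gr, n_nulls = 10, seed = 2)
  rel <- assemble_features(gr, p, scheme = "g_global", relative = TRUE,
                           nulls = nulls)
  expect_length(rel, 4L)
  expect_named(rel, c("modularity", "z", "y", "assortativity"))
  # the actual graph is more modular than its rewired nulls
  expect_gt(rel[["modularity"]], 0)
  zones <- structural_zones(m$positions, m$geometry)
  fz <- assemble_features(gr, p, scheme = "g_zonewise", zones = zones)
  n_zones <- length(unique(as.character(zones)))
  expect_length(fz, 1 + 3 * n_zones)
})
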