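# Z-scoring, profiles, median profiles, averaged maps, cumulative
# strength, downsampling, bootstrap CIs and the granule-cell count.

test_that("z-scores follow (A - X) / sigma", {
  m <- toy_map(matrix(5, 4, 6))
  z <- compute_zscore_map(m, noise_mean = 5, noise_sd = 2)
  expect_true(all(z$z == 0))
  m2 <- toy_map(matrix(11, 4, 6))
  z2 <- compute_zscore_map(m2, noise_mean = 5, noise_sd = 2)
  expect_true(all(z2$z == 3))
  expect_error(compute_zscore_map(m, noise_mean = 5, noise_sd = 0),
               "sigma")
})

test_that("z-score maps are invariant under positive affine rescaling", {
  set.seed(31)
  amp <- matrix(runif(6 * 16, 0, 100), 6, 16)
  m <- toy_map(amp)
  tr <- generate_trials(m, n_trials = 8, noise_sd = 4, noise_mean = 6,
                        seed = 2)
  z0 <- compute_zscore_map(m, trials = tr)$z
  for (k in 1:5) {
    a <- runif(1, 0.2, 5); b <- runif(1, -3, 10)
    tr2 <- tr
    tr2$evoked <- lapply(tr$evoked, function(v) a * v + b)
    tr2$noise <- lapply(tr$noise, function(v) a * v + b)
    z1 <- compute_zscore_map(m, trials = tr2)$z
    expect_equal(z1, z0, tolerance = 1e-10)
  }
})

test_that("profiles take the column-wise maximum and flag connectivity", {
  amp <- matrix(5, 6, 16)
  amp[3, 7] <- 80
  m <- toy_map(amp)
  zm <- compute_zscore_map(m, noise_mean = 5, noise_sd = 3)
  p <- project_profile(m, zm, "max_z")
  expect_equal(p$value[7], (80 - 5) / 3)
  expect_equal(which(p$connected), 7L)
  pw <- project_profile(m, zm, "max_weight")
  expect_equal(pw$value[7], 80)
  expect_true(all(is.na(pw$value[-7])))
  # all-noise map: no connected columns
  zn <- compute_zscore_map(toy_map(matrix(5, 6, 16)), noise_mean = 5,
                           noise_sd = 3)
  expect_false(any(project_profile(m, zn, "max_z")$connected[-7]))
  # random grid equals the brute-force column maximum
  set.seed(8)
  amp <- matrix(runif(6 * 16, 0, 60), 6, 16)
  m <- toy_map(amp)
  zm <- compute_zscore_map(m, noise_mean = 6, noise_sd = 3)
  p <- project_profile(m, zm, "max_z")
  oracle <- vapply(seq_len(16), function(j) {
    mx <- -Inf
    for (i in 1:6) mx <- max(mx, zm$z[i, j])
    mx
  }, numeric(1))
  expect_equal(p$value, oracle)
})

test_that("median profiles preserve constants and match a sort oracle", {
  m <- toy_map(matrix(runif(96, 0, 50), 6, 16))
  zm <- compute_zscore_map(m, noise_mean = 6, noise_sd = 3)
  p <- project_profile(m, zm, "max_z")
  # identical profiles: median equals the (smoothed) input, MAD = 0
  mp <- median_profile(list(p, p, p))
  expect_true(all(mp$mad == 0))
  expect_equal(mp$n, rep(3, nrow(mp)))
  # constant profile: unit-area kernel leaves the constant untouched
  pc <- p; pc$value <- 7
  mpc <- median_profile(list(pc, pc))
  expect_equal(mpc$median, rep(7, nrow(mpc)))
  # three step profiles: pointwise median equals a per-position sort
  ps <- lapply(c(1, 5, 9), function(v) { q <- p; q$value <- v; q })
  mps <- median_profile(ps)
  expect_equal(mps$median, rep(5, nrow(mps)))
})

test_that("averaged maps reduce to their inputs in degenerate cases", {
  g <- mean_geometry()
  amp <- matrix(runif(6 * 16, 0, 50), 6, 16)
  m <- toy_map(amp, geometry = g)
  # one map with bins equal to the site size reproduces the input
  a1 <- average_map(list(m), bin_width = 20)
  expect_equal(a1$values[, seq_len(16)], amp, ignore_attr = TRUE)
  # two identical maps average to either
  a2 <- average_map(list(m, m), bin_width = 20)
  expect_equal(a2$values[, seq_len(16)], amp, ignore_attr = TRUE)
  # two maps with known values in one bin give the hand mean
  amp2 <- amp + 10
  a3 <- average_map(list(m, toy_map(amp2, geometry = g)), bin_width = 20)
  expect_equal(a3$values[3, 4], (amp[3, 4] + amp2[3, 4]) / 2)
})

test_that("cumulative strength accumulates connected weights in nA", {
  g <- mean_geometry()
  amp <- matrix(5, 6, 16)
  m <- toy_map(amp, geometry = g)
  zm <- compute_zscore_map(m, noise_mean = 5, noise_sd = 3)
  flat <- cumulative_strength(project_profile(m, zm, "max_weight"))
  expect_true(all(flat$cumulative_nA == 0))
  amp[2, 4] <- 500; amp[5, 11] <- 500
  m2 <- toy_map(amp, geometry = g)
  zm2 <- compute_zscore_map(m2, noise_mean = 5, noise_sd = 3)
  cc <- cumulative_strength(project_profile(m2, zm2, "max_weight"))
  expect_equal(max(cc$cumulative_nA), 1.0)
  # random profile: non-decreasing, final value = sum of connected maxima
  set.seed(13)
  amp3 <- matrix(runif(96, 0, 40), 6, 16)
  m3 <- toy_map(amp3, geometry = g)
  zm3 <- compute_zscore_map(m3, noise_mean = 6, noise_sd = 3)
  p3 <- project_profile(m3, zm3, "max_weight")
  c3 <- cumulative_strength(p3)
  expect_true(all(diff(c3$cumulative_nA) >= 0))
  expect_equal(max(c3$cumulative_nA),
               sum(p3$value[p3$connected]) / 1000)
})

test_that("downsampling is an exact 2x2 block mean", {
  g <- mean_geometry()
  ones <- toy_map(matrix(1, 4, 4), geometry = g)
  d1 <- downsample_map(ones)
  expect_equal(d1$amplitudes, matrix(1, 2, 2))
  expect_equal(d1$site_size, 40)
  blk <- toy_map(matrix(c(1, 5, 3, 7), 2, 2), geometry = g)
  expect_equal(as.numeric(downsample_map(blk)$amplitudes), 4)
  # random grid equals the explicit block-mean oracle
  set.seed(17)
  amp <- matrix(runif(6 * 16), 6, 16)
  d <- downsample_map(toy_map(amp, geometry = g))
  oracle <- matrix(0, 3, 8)
  for (i in 1:3) for (j in 1:8) {
    oracle[i, j] <- mean(amp[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(d$amplitudes, oracle)
  # block-mean conservation: 4 * sum(downsampled) == sum(original)
  expect_equal(4 * sum(d$amplitudes), sum(amp))
  # odd column count pads by edge replication
  odd <- downsample_map(toy_map(amp[, 1:15], geometry = g))
  expect_equal(ncol(odd$amplitudes), 8L)
})

test_that("bootstrap profile CIs collapse and match exhaustive resampling", {
  g <- mean_geometry()
  mk <- function(v) {
    m <- toy_map(matrix(v, 6, 4, byrow = TRUE), geometry = g)
    zm <- compute_zscore_map(m, noise_mean = 6, noise_sd = 3)
    project_profile(m, zm, "max_z")
  }
  p <- mk(c(10, 20, 30, 40))
  ci0 <- bootstrap_profile_ci(list(p, p, p), n_boot = 200, seed = 1)
  expect_equal(ci0$lower, ci0$upper)
  # alpha = 1 collapses to the point estimate
  ps <- lapply(c(1, 2, 3, 4, 5), function(k) mk(k * c(1, 2, 3, 4)))
  ci1 <- bootstrap_profile_ci(ps, n_boot = 100, alpha = 1, seed = 1)
  expect_equal(ci1$lower, ci1$median)
  expect_equal(ci1$upper, ci1$median)
  # exhaustive oracle over all 5^5 resamples at one position
  vals <- sapply(ps, function(p) p$value[1])
  grid <- as.matrix(expand.grid(rep(list(1:5), 5)))
  meds <- apply(grid, 1, function(ix) median(vals[ix]))
  ci <- bootstrap_profile_ci(ps, n_boot = 4000, alpha = 0.05, seed = 2)
  expect_equal(ci$lower[1], quantile(meds, 0.025, names = FALSE),
               tolerance = 0.15)
  expect_equal(ci$upper[1], quantile(meds, 0.975, names = FALSE),
               tolerance = 0.15)
})

test_that("the photostimulated granule-cell estimate matches the printed arithmetic", {
  expect_equal(estimate_activated_gc_count(20, 100, 1.92e6), 76.8)
  # the published low-resolution count uses the stated stimulated volume
  # of 2e-4 mm^3 for a 40-um site
  expect_equal(estimate_activated_gc_count(40, volume_mm3 = 2e-4), 384)
  # strict side^2 x depth arithmetic scales by 4 between resolutions
  expect_equal(estimate_activated_gc_count(40, 100, 1.92e6), 4 * 76.8)
  expect_equal(estimate_activated_gc_count(20, 100, 0), 0)
})

test_that("active-site statistics count thresholded sites by side", {
  g <- mean_geometry()
  amp <- matrix(5, 6, 16)
  m <- toy_map(amp, geometry = g)
  zm <- compute_zscore_map(m, noise_mean = 5, noise_sd = 3)
  s0 <- active_site_stats(zm, m)
  expect_equal(s0$fraction_active, 0)
  expect_length(s0$amplitudes, 0)
  amp[1:6, 1:2] <- 50   # 12 active sites of 96
  m1 <- toy_map(amp, geometry = g)
  zm1 <- compute_zscore_map(m1, noise_mean = 5, noise_sd = 3)
  s1 <- active_site_stats(zm1, m1)
  expect_equal(s1$fraction_active, 0.125)
  expect_equal(s1$contra$n_active, 12)   # columns 1:2 are contralateral
  expect_equal(s1$ipsi$n_active, 0)
  # random z map equals a brute-force count
  set.seed(23)
  amp2 <- matrix(runif(96, 0, 30), 6, 16)
  m2 <- toy_map(amp2, geometry = g)
  zm2 <- compute_zscore_map(m2, noise_mean = 6, noise_sd = 3)
  s2 <- active_site_stats(zm2, m2)
  cnt <- 0
  for (i in 1:6) for (j in 1:16) if (zm2$z[i, j] >= 3) cnt <- cnt + 1
  expect_equal(s2$n_active, cnt)
})
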