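# Map-level processing: z-scoring against the recording noise, synaptic
# profiles, group median profiles, averaged maps, cumulative strength
# curves and downsampling. All amplitudes are EPSC magnitudes in pA.

#' Construct a connectivity map
#'
#' A connectivity map holds the grid of mean evoked EPSC amplitudes of one
#' recorded Purkinje cell: rows index depth in the granule-cell layer,
#' columns index positions along the mediolateral axis.
#'
#' @param amplitudes numeric matrix of mean EPSC amplitudes (pA,
#'   magnitudes, >= 0), rows x columns.
#' @param site_size photostimulation site side (um), 20 or 40.
#' @param positions column centre positions (um, signed, ipsilateral
#'   positive); strictly increasing, length `ncol(amplitudes)`.
#' @param geometry a [zebrin_geometry()].
#' @param condition,map_id,subject_id metadata strings.
#' @param active planted logical matrix of truly active sites (optional,
#'   synthetic maps only).
#' @return object of class `connectivity_map`.
#' @export
connectivity_map <- function(amplitudes, site_size, positions, geometry,
                             condition = NA_character_,
                             map_id = NA_character_,
                             subject_id = NA_character_,
                             active = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (!site_size %in% c(20, 40)) stop("`site_size` must be 20 or 40 um")
  if (length(positions) != ncol(amplitudes)) {
    stop("`positions` must have one entry per column")
  }
  if (any(diff(positions) <= 0)) stop("`positions` must be strictly increasing")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be finite non-negative magnitudes")
  }
  stopifnot(inherits(geometry, "zebrin_geometry"))
  structure(
    list(amplitudes = amplitudes, site_size = site_size,
         positions = as.numeric(positions), geometry = geometry,
         condition = condition, map_id = map_id, subject_id = subject_id,
         active = active),
    class = "connectivity_map"
  )
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("Connectivity map %s (%s): %d x %d sites of %g um, [%g, %g] um\n",
              x$map_id, x$condition, nrow(x$amplitudes), ncol(x$amplitudes),
              x$site_size, min(x$positions), max(x$positions)))
  invisible(x)
}

#' Z-score a map against its noise distribution
#'
#' Each site's mean evoked amplitude A is standardised against the pooled
#' map-wide synaptic-noise distribution: z = (A - X) / sigma, with X and
#' sigma the mean and SD of the noise amplitudes collected at every site
#' of the map. Sites with z >= `threshold` (default 3) are considered
#' synaptically connected.
#'
#' @param map a [connectivity_map()] (its grid supplies A when `trials` is
#'   absent).
#' @param trials optional trial set from [generate_trials()]; when given,
#'   A is the per-site mean of the evoked draws and the noise statistics
#'   are estimated from the pooled per-site noise draws.
#' @param noise_mean,noise_sd noise statistics (pA), required when
#'   `trials` is absent.
#' @param threshold z threshold for calling a site active.
#' @return object of class `zscore_map`: fields `z` (matrix), `noise_mean`,
#'   `noise_sd`, `threshold`.
#' @export
compute_zscore_map <- function(map, trials = NULL, noise_mean = NULL,
                               noise_sd = NULL, threshold = 3) {
  stopifnot(inherits(map, "connectivity_map"))
  if (!is.null(trials)) {
    stopifnot(inherits(trials, "trial_set"))
    A <- matrix(vapply(trials$evoked, mean, numeric(1)),
                nrow = nrow(map$amplitudes))
    noise <- unlist(trials$noise, use.names = FALSE)
    if (length(noise) < 2L) stop("need >= 2 noise samples to estimate sigma")
    noise_mean <- mean(noise)
    noise_sd <- stats::sd(noise)
  } else {
    if (is.null(noise_mean) || is.null(noise_sd)) {
      stop("supply `trials` or both `noise_mean` and `noise_sd`")
    }
    A <- map$amplitudes
  }
  if (noise_sd <= 0) stop("degenerate noise: sigma must be > 0")
  structure(
    list(z = (A - noise_mean) / noise_sd, noise_mean = noise_mean,
         noise_sd = noise_sd, threshold = threshold),
    class = "zscore_map"
  )
}

#' Project a map onto its mediolateral synaptic profile
#'
#' Collapses each granule-cell-layer column to a single value: the maximum
#' z score over the column (`mode = "max_z"`), or the maximum amplitude
#' among the column's significant (z >= threshold) sites
#' (`mode = "max_weight"`). Columns without any significant site are
#' flagged not-connected; in weight mode their value is `NA`.
#'
#' @param map a [connectivity_map()].
#' @param zmap the matching [compute_zscore_map()] result.
#' @param mode `"max_z"` or `"max_weight"`.
#' @return object of class `synaptic_profile`: data.frame with columns
#'   `position_um`, `position_norm` (percent of the ipsilateral P1- band),
#'   `value`, `connected`; attributes `mode`, `site_size`.
#' @export
project_profile <- function(map, zmap, mode = c("max_z", "max_weight")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "connectivity_map"), inherits(zmap, "zscore_map"))
  if (!all(dim(zmap$z) == dim(map$amplitudes))) {
    stop("z map and amplitude grid shapes differ")
  }
  thr <- zmap$threshold
  connected <- apply(zmap$z >= thr, 2, any)
  value <- if (mode == "max_z") {
    apply(zmap$z, 2, max)
  } else {
    vapply(seq_len(ncol(map$amplitudes)), function(j) {
      sig <- zmap$z[, j] >= thr
      if (!any(sig)) NA_real_ else max(map$amplitudes[sig, j])
    }, numeric(1))
  }
  out <- data.frame(
    position_um = map$positions,
    position_norm = align_to_zebrin(map$positions, map$geometry),
    value = value,
    connected = connected
  )
  structure(out, mode = mode, site_size = map$site_size,
            class = c("synaptic_profile", "data.frame"))
}

# unit-area triangular kernel on a regular grid
.triangular_kernel <- function(half_width, step) {
  n <- max(1L, floor(half_width / step))
  k <- 1 - abs(seq(-n, n)) * step / half_width
  k[k < 0] <- 0
  k / sum(k)
}

# convolve keeping length, renormalising at the edges so a constant
# profile stays exactly constant
.convolve_same <- function(x, kernel) {
  n <- length(x); m <- length(kernel); h <- (m - 1L) %/% 2L
  xp <- c(rep(NA_real_, h), x, rep(NA_real_, h))
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- kernel
    seg <- xp[i:(i + m - 1L)]
    ok <- !is.na(seg)
    out[i] <- if (any(ok)) sum(seg[ok] * w[ok]) / sum(w[ok]) else NA_real_
  }
  out
}

#' Group median profile with MAD envelope
#'
#' Each profile is linearly interpolated onto a common normalised axis
#' (1-um-equivalent step), convolved with a unit-area triangular kernel
#' (half-width 9 um for 20-um maps, 18 um for 40-um maps), then reduced to
#' the pointwise median and raw median absolute deviation across maps.
#' Positions covered by fewer than half of the maps are dropped.
#'
#' @param profiles list of [project_profile()] results at one resolution.
#' @param half_width kernel half-width (um); default 9 or 18 by site size.
#' @param fill value used for not-connected columns of weight-mode
#'   profiles before smoothing (default 0).
#' @return object of class `median_profile`: data.frame with columns
#'   `position_norm`, `median`, `mad`, `n`.
#' @export
median_profile <- function(profiles, half_width = NULL, fill = 0) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  sizes <- vapply(profiles, function(p) attr(p, "site_size"), numeric(1))
  if (length(unique(sizes)) != 1L) stop("profiles mix map resolutions")
  site_size <- sizes[[1]]
  if (is.null(half_width)) half_width <- if (site_size == 20) 9 else 18
  # 1-um-equivalent step on the normalised axis, using each profile's own
  # norm scale; use the median um->% factor so the axis is shared
  scale <- stats::median(vapply(profiles, function(p) {
    stats::median(diff(p$position_norm) / diff(p$position_um))
  }, numeric(1)))
  step <- 1 * scale   # percent per um-equivalent
  lo <- min(vapply(profiles, function(p) min(p$position_norm), numeric(1)))
  hi <- max(vapply(profiles, function(p) max(p$position_norm), numeric(1)))
  axis <- seq(lo, hi, by = step)
  kernel <- .triangular_kernel(half_width * scale, step)
  mat <- vapply(profiles, function(p) {
    v <- p$value
    if (attr(p, "mode") == "max_weight") v[!p$connected] <- fill
    y <- stats::approx(p$position_norm, v, xout = axis, rule = 1)$y
    .convolve_same(y, kernel)
  }, numeric(length(axis)))
  n_cov <- rowSums(!is.na(mat))
  keep <- n_cov >= ceiling(length(profiles) / 2)
  med <- apply(mat[keep, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  madv <- apply(mat[keep, , drop = FALSE], 1, function(r) {
    stats::median(abs(r - stats::median(r, na.rm = TRUE)), na.rm = TRUE)
  })
  structure(
    data.frame(position_norm = axis[keep], median = med, mad = madv,
               n = n_cov[keep]),
    site_size = site_size, half_width = half_width,
    class = c("median_profile", "data.frame")
  )
}

#' Averaged map over a group
#'
#' Pools all site amplitudes of the maps with their normalised positions,
#' sorts by position, and averages within fixed-width bins (30-um
#' equivalents for 20-um maps, 60 for 40-um maps) separately per grid row.
#' Empty bins are reported as `NA`, never as zero.
#'
#' @param maps list of [connectivity_map()]s at one resolution.
#' @param bin_width bin width in um equivalents (default 30 or 60 by
#'   resolution).
#' @return object of class `averaged_map`: list with `values` (rows x
#'   bins matrix), `bin_centers` (normalised units), `bin_width`, `n_maps`.
#' @export
average_map <- function(maps, bin_width = NULL) {
  if (length(maps) < 1L) stop("need >= 1 map")
  sizes <- vapply(maps, function(m) m$site_size, numeric(1))
  if (length(unique(sizes)) != 1L) stop("maps mix resolutions")
  site_size <- sizes[[1]]
  if (is.null(bin_width)) bin_width <- if (site_size == 20) 30 else 60
  n_rows <- unique(vapply(maps, function(m) nrow(m$amplitudes), integer(1)))
  if (length(n_rows) != 1L) stop("maps have differing row counts")
  scale <- stats::median(vapply(maps, function(m) {
    100 / m$geometry$band_widths[["P1-_ipsi"]]
  }, numeric(1)))
  bw <- bin_width * scale
  pos <- unlist(lapply(maps, function(m) align_to_zebrin(m$positions, m$geometry)))
  lo <- min(pos)
  # tolerance keeps sites that land exactly on a bin edge in the bin to
  # their right, robustly to floating-point placement
  bin <- floor((pos - lo) / bw + 1e-9) + 1L
  n_bins <- max(bin)
  vals <- matrix(NA_real_, n_rows, n_bins)
  for (r in seq_len(n_rows)) {
    v <- unlist(lapply(maps, function(m) m$amplitudes[r, ]))
    agg <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
    vals[r, ] <- as.numeric(agg)
  }
  structure(
    list(values = vals,
         bin_centers = lo + (seq_len(n_bins) - 0.5) * bw,
         bin_width = bin_width, n_maps = length(maps)),
    class = "averaged_map"
  )
}

#' Cumulative synaptic strength along the mediolateral axis
#'
#' Running sum, from the contralateral end, of each column's maximal
#' significant synaptic weight, converted to nA. Not-connected columns
#' contribute zero, so the curve is non-decreasing.
#'
#' @param profile a weight-mode [project_profile()] result.
#' @return data.frame with columns `position_um`, `position_norm`,
#'   `cumulative_nA`.
#' @export
cumulative_strength <- function(profile) {
  stopifnot(inherits(profile, "synaptic_profile"))
  if (attr(profile, "mode") != "max_weight") {
    stop("cumulative strength requires a weight-mode profile")
  }
  w <- profile$value
  w[!profile$connected | is.na(w)] <- 0
  data.frame(
    position_um = profile$position_um,
    position_norm = profile$position_norm,
    cumulative_nA = cumsum(w) / 1000
  )
}

#' Downsample a high-resolution map to low resolution
#'
#' Convolves the 20-um grid with a 2 x 2 box kernel and decimates by
#' (2, 2): each output site is the mean of its 2 x 2 block. Odd row or
#' column counts are padded by edge replication first.
#'
#' @param map a [connectivity_map()] with `site_size = 20`.
#' @return a [connectivity_map()] with `site_size = 40`.
#' @export
downsample_map <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  if (map$site_size != 20) stop("`map` must be a 20-um (high-resolution) map")
  a <- map$amplitudes
  pos <- map$positions
  if (nrow(a) %% 2L == 1L) a <- rbind(a, a[nrow(a), ])
  if (ncol(a) %% 2L == 1L) {
    a <- cbind(a, a[, ncol(a)])
    pos <- c(pos, pos[length(pos)] + map$site_size)
  }
  nr <- nrow(a) %/% 2L; nc <- ncol(a) %/% 2L
  out <- 0.25 * (a[2 * seq_len(nr) - 1L, 2 * seq_len(nc) - 1L, drop = FALSE] +
                 a[2 * seq_len(nr) - 1L, 2 * seq_len(nc), drop = FALSE] +
                 a[2 * seq_len(nr), 2 * seq_len(nc) - 1L, drop = FALSE] +
                 a[2 * seq_len(nr), 2 * seq_len(nc), drop = FALSE])
  new_pos <- (pos[2 * seq_len(nc) - 1L] + pos[2 * seq_len(nc)]) / 2
  connectivity_map(out, 40, new_pos, map$geometry, map$condition,
                   map_id = map$map_id, subject_id = map$subject_id)
}

#' Bootstrap confidence interval of the group median profile
#'
#' Resamples maps (profiles) with replacement and recomputes the pointwise
#' median; returns percentile confidence bounds. A position is connected
#' at the group level if the lower bound exceeds zero.
#'
#' @param profiles list of [project_profile()] results (>= 3), all on the
#'   same column grid.
#' @param n_boot number of bootstrap resamples.
#' @param alpha two-sided miss probability (0.05 gives a 95 percent CI).
#' @param seed integer seed.
#' @param fill replacement for not-connected weight-mode columns.
#' @return data.frame with `position_um`, `median`, `lower`, `upper`,
#'   `group_connected`.
#' @export
bootstrap_profile_ci <- function(profiles, n_boot = 1000, alpha = 0.05,
                                 seed = 1, fill = 0) {
  if (length(profiles) < 3L) stop("need >= 3 profiles")
  vals <- vapply(profiles, function(p) {
    v <- p$value
    if (attr(p, "mode") == "max_weight") v[!p$connected] <- fill
    v
  }, numeric(nrow(profiles[[1]])))
  set.seed(seed)
  n <- ncol(vals)
  meds <- matrix(NA_real_, n_boot, nrow(vals))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    meds[b, ] <- apply(vals[, idx, drop = FALSE], 1, stats::median)
  }
  point <- apply(vals, 1, stats::median)
  lower <- apply(meds, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  upper <- apply(meds, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  if (alpha >= 1) { lower <- point; upper <- point }
  data.frame(
    position_um = profiles[[1]]$position_um,
    median = point, lower = lower, upper = upper,
    group_connected = lower > 0
  )
}

#' Expected number of photostimulated granule cells per site
#'
#' Volume of the stimulated column (site side squared times effective
#' light-penetration depth) converted to cubic millimetres and multiplied
#' by the granule-cell density.
#'
#' @param site_side photostimulation site side (um).
#' @param depth effective depth of photostimulation (um), default 100.
#' @param density granule cells per cubic mm, default 1.92e6.
#' @param volume_mm3 optional stimulated volume (mm^3) entered directly;
#'   overrides the `site_side^2 * depth` computation.
#' @return expected granule-cell count (may be fractional).
#' @export
estimate_activated_gc_count <- function(site_side, depth = 100,
                                        density = 1.92e6,
                                        volume_mm3 = NULL) {
  stopifnot(density >= 0)
  if (is.null(volume_mm3)) {
    stopifnot(site_side > 0, depth > 0)
    volume_mm3 <- site_side^2 * depth * 1e-9
  }
  volume_mm3 * density
}

#' Active-site statistics of a thresholded map
#'
#' @param zmap a [compute_zscore_map()] result.
#' @param map the matching [connectivity_map()].
#' @return list with `fraction_active`, `n_active`, `n_sites`,
#'   `amplitudes` (significant-site amplitudes for pooling), and
#'   `ipsi`/`contra` per-side active counts and amplitude lists.
#' @export
active_site_stats <- function(zmap, map) {
  stopifnot(inherits(zmap, "zscore_map"), inherits(map, "connectivity_map"))
  if (!all(dim(zmap$z) == dim(map$amplitudes))) stop("shape mismatch")
  act <- zmap$z >= zmap$threshold
  side <- matrix(rep(sign(map$positions), each = nrow(act)), nrow = nrow(act))
  list(
    fraction_active = mean(act),
    n_active = sum(act),
    n_sites = length(act),
    amplitudes = map$amplitudes[act],
    ipsi = list(n_active = sum(act & side > 0),
                amplitudes = map$amplitudes[act & side > 0]),
    contra = list(n_active = sum(act & side < 0),
                  amplitudes = map$amplitudes[act & side < 0])
  )
}
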