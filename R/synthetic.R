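# Synthetic cohorts of connectivity maps with planted condition effects
# and map-to-behaviour couplings. The generator emulates the study
# conditions: patchy activation on a 20- or 40-um photostimulation grid,
# condition-specific distributions of significant synaptic weights,
# zebrin geometries drawn from the printed band statistics, and
# behavioural features generated from the graph features through the
# interaction GLM the analysis fits.

# Per-condition defaults: map counts (high-resolution groups), mean/SD of
# the significant synaptic weights (pA), and mean fraction of active
# sites, all as printed for the seven locomotor conditions.
.condition_defaults <- data.frame(
  condition = c("control", "short_training", "long_training", "early_sham",
                "early_cuff", "adapted_sham", "adapted_cuff"),
  n_maps = c(14L, 13L, 11L, 11L, 25L, 14L, 17L),
  amp_mean = c(72.3, 89.8, 86.7, 91.9, 78.7, 116.2, 88.8),
  amp_sd = c(50, 71, 48.3, 60, 62, 69, 59),
  frac_active = c(0.124, 0.116, 0.099, 0.142, 0.165, 0.133, 0.153),
  group_code = c(0, -1, 1, -1, -1, 1, 1),
  stringsAsFactors = FALSE
)

#' Solve truncated-lognormal parameters for target moments
#'
#' Finds `(meanlog, sdlog)` such that a lognormal truncated below at
#' `lower` has the requested mean and SD. Used so that the generated
#' *significant* (supra-threshold) synaptic weights reproduce the printed
#' condition means exactly in expectation, despite detection truncation.
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lower truncation point (same units).
#' @return list with `meanlog`, `sdlog`, `lower`, and the achieved
#'   `mean` and `sd`.
#' @export
calibrate_truncated_lognormal <- function(mean, sd, lower) {
  stopifnot(mean > lower, sd > 0, lower >= 0)
  la <- if (lower > 0) log(lower) else -Inf
  moments <- function(mu, sg) {
    if (!is.finite(la)) {
      m1 <- exp(mu + sg^2 / 2)
      m2 <- exp(2 * mu + 2 * sg^2)
    } else {
      z0 <- (mu - la) / sg
      m1 <- exp(mu + sg^2 / 2) * stats::pnorm(z0 + sg) / stats::pnorm(z0)
      m2 <- exp(2 * mu + 2 * sg^2) * stats::pnorm(z0 + 2 * sg) / stats::pnorm(z0)
    }
    c(m1, sqrt(pmax(m2 - m1^2, 0)))
  }
  # untruncated moment match as the starting point
  sl2 <- log(1 + (sd / mean)^2)
  start <- c(log(mean) - sl2 / 2, log(sqrt(sl2)))
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] / mean - 1)^2 + (mm[2] / sd - 1)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1]; sg <- exp(fit$par[2])
  mm <- moments(mu, sg)
  list(meanlog = mu, sdlog = sg, lower = lower, mean = mm[1], sd = mm[2])
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, lower) {
  p0 <- if (lower > 0) stats::plnorm(lower, meanlog, sdlog) else 0
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, meanlog, sdlog)
}

#' Cohort configuration
#'
#' Bundles every knob of the synthetic generator. Defaults reproduce the
#' study conditions: seven locomotor groups with the published map counts
#' (105 high-resolution maps in total), per-condition significant-weight
#' distributions and active-site fractions, a 20-um grid of 6 rows by 64
#' columns spanning 1280 um of the mediolateral axis, and a Gaussian
#' noise model whose 3-sigma detection point sits at about 15 pA.
#'
#' @param conditions data.frame with columns `condition`, `n_maps`,
#'   `amp_mean`, `amp_sd`, `frac_active`, `group_code`.
#' @param resolution site size in um, 20 or 40.
#' @param noise_mean,noise_sd synaptic-noise model (pA).
#' @param frac_sd between-map SD of the active-site fraction.
#' @param patch_centers,patch_center_sds,patch_center_weights mixture
#'   prior (um, zebrin frame) for patch centre placement; the default
#'   puts mass near the mid-ipsilateral hotspot (~500 um), the midline
#'   and the contralateral side.
#' @param patch_ml_radius,patch_row_radius ranges (um / rows) for the
#'   jittered elliptical patch extents.
#' @param n_trials trials per site for trial-level generation.
#' @param glm_coef planted behaviour model: list with `beta0`, `beta`,
#'   `gamma` (recycled to the feature dimension when scalar).
#' @param behavior_noise_sd SD of the behavioural error term.
#' @param seed global seed for the cohort.
#' @return object of class `cohort_config` (a list).
#' @export
cohort_config <- function(conditions = .condition_defaults,
                          resolution = 20,
                          noise_mean = 6, noise_sd = 3,
                          frac_sd = 0.05,
                          patch_centers = c(500, 0, -400),
                          patch_center_sds = c(120, 120, 200),
                          patch_center_weights = c(0.4, 0.35, 0.25),
                          patch_ml_radius = c(40, 120),
                          patch_row_radius = c(1, 2.5),
                          n_trials = 7,
                          glm_coef = list(beta0 = 0.3,
                                          beta = c(1.5, -0.8, 0.6, 0.4,
                                                   -0.5, 0.3, 0.2),
                                          gamma = c(0.4, 0, -0.3, 0.2,
                                                    0, 0.1, 0)),
                          behavior_noise_sd = 0.1,
                          seed = 1L) {
  if (!resolution %in% c(20, 40)) stop("`resolution` must be 20 or 40")
  stopifnot(all(conditions$n_maps >= 1), noise_sd > 0,
            n_trials >= 5, n_trials <= 10)
  rownames(conditions) <- NULL
  n_rows <- if (resolution == 20) 6L else 4L
  n_cols <- if (resolution == 20) 64L else 32L
  structure(
    list(conditions = conditions, resolution = resolution,
         n_rows = n_rows, n_cols = n_cols,
         noise_mean = noise_mean, noise_sd = noise_sd, frac_sd = frac_sd,
         patch_centers = patch_centers, patch_center_sds = patch_center_sds,
         patch_center_weights = patch_center_weights,
         patch_ml_radius = patch_ml_radius,
         patch_row_radius = patch_row_radius,
         n_trials = n_trials, glm_coef = glm_coef,
         behavior_noise_sd = behavior_noise_sd,
         detection_threshold = 3,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate one synthetic connectivity map
#'
#' Builds a grid of mean EPSC amplitudes as background noise plus patchy
#' activation: elliptical patches with jittered extents are placed at
#' centres drawn from the condition's spatial prior (in zebrin
#' coordinates) until the map's target number of active sites is reached,
#' and active sites receive amplitudes from the condition's calibrated
#' truncated-lognormal weight distribution.
#'
#' @param condition condition label present in `config$conditions`.
#' @param geometry a [zebrin_geometry()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param amp_scale multiplier on planted patch amplitudes (0 gives a
#'   pure-noise map).
#' @return a [connectivity_map()] with the planted `active` mask and
#'   attribute `planted_amplitudes`.
#' @export
generate_map <- function(condition, geometry, config, seed = 1,
                         amp_scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  row <- config$conditions[config$conditions$condition == condition, ]
  if (nrow(row) != 1L) stop("unknown condition label: ", condition)
  set.seed(seed)
  nr <- config$n_rows; nc <- config$n_cols; ss <- config$resolution
  positions <- (seq_len(nc) - (nc + 1) / 2) * ss
  # background: noise-level means everywhere
  amp <- matrix(pmax(stats::rnorm(nr * nc, config$noise_mean,
                                  config$noise_sd), 0), nr, nc)
  # target active-site count
  frac <- stats::rnorm(1, row$frac_active, config$frac_sd)
  frac <- min(max(frac, 0.01), 0.6)
  target <- round(frac * nr * nc)
  active <- matrix(FALSE, nr, nc)
  tries <- 0L
  while (sum(active) < target && tries < 100L) {
    tries <- tries + 1L
    comp <- sample.int(length(config$patch_centers), 1,
                       prob = config$patch_center_weights)
    cx <- stats::rnorm(1, config$patch_centers[comp],
                       config$patch_center_sds[comp])
    cy <- stats::runif(1, 1, nr)
    rx <- stats::runif(1, config$patch_ml_radius[1], config$patch_ml_radius[2])
    ry <- stats::runif(1, config$patch_row_radius[1],
                       config$patch_row_radius[2])
    d <- outer(seq_len(nr), seq_len(nc), function(r, c) {
      ((positions[c] - cx) / rx)^2 + ((r - cy) / ry)^2
    })
    active <- active | (d <= 1)
  }
  # trim overshoot so the planted fraction stays near target
  excess <- sum(active) - target
  if (excess > 0) {
    on <- which(active)
    active[sample(on, excess)] <- FALSE
  }
  n_act <- sum(active)
  planted <- numeric(0)
  if (n_act > 0 && amp_scale > 0) {
    cal <- calibrate_truncated_lognormal(
      row$amp_mean, row$amp_sd,
      lower = config$noise_mean +
        config$detection_threshold * config$noise_sd)
    planted <- amp_scale * .rtrunc_lnorm(n_act, cal$meanlog, cal$sdlog,
                                         cal$lower)
    amp[active] <- planted
  }
  m <- connectivity_map(amp, ss, positions, geometry,
                        condition = condition,
                        map_id = sprintf("%s_%06d", condition, seed))
  m$active <- active
  attr(m, "planted_amplitudes") <- planted
  m
}

#' Generate per-site repeated trials for a map
#'
#' Draws `n_trials` evoked amplitudes per site, centred on the site's
#' mean amplitude, and one noise amplitude per trial and site from the
#' noise model, emulating the repeated photostimulation protocol (5-10
#' stimulations per site).
#'
#' @param map a [connectivity_map()].
#' @param n_trials trials per site, between 5 and 10.
#' @param noise_sd trial-to-trial SD (pA) of both evoked and noise draws.
#' @param noise_mean mean of the noise amplitudes (pA).
#' @param seed integer seed.
#' @return object of class `trial_set`: list with `evoked` and `noise`
#'   (lists of per-site draws, column-major site order) and `dim`.
#' @export
generate_trials <- function(map, n_trials = 7, noise_sd = 3,
                            noise_mean = 6, seed = 1) {
  stopifnot(inherits(map, "connectivity_map"))
  if (n_trials < 5 || n_trials > 10) stop("`n_trials` must be in [5, 10]")
  set.seed(seed)
  mu <- as.numeric(map$amplitudes)   # column-major
  evoked <- lapply(mu, function(m) stats::rnorm(n_trials, m, noise_sd))
  noise <- lapply(mu, function(m) stats::rnorm(n_trials, noise_mean,
                                               noise_sd))
  structure(list(evoked = evoked, noise = noise, dim = dim(map$amplitudes),
                 n_trials = n_trials),
            class = "trial_set")
}

#' Generate behavioural features from graph features
#'
#' Inverts the behaviour-prediction model: for map i with feature vector
#' G_i and group code T_i in \{+1, -1\},
#' Y_i = beta0 + sum_j beta_j G_ji + sum_j gamma_j T_i G_ji + eps_i with
#' Gaussian noise eps.
#'
#' @param features numeric matrix (maps x features) or data.frame.
#' @param coef list with `beta0` (scalar), `beta`, `gamma` (length =
#'   feature dimension; scalars are recycled).
#' @param group_codes vector of +1/-1 group codes, one per map.
#' @param noise_sd SD of the error term (target units).
#' @param seed integer seed.
#' @return numeric vector of behavioural features.
#' @export
generate_behavior <- function(features, coef, group_codes, noise_sd = 0,
                              seed = 1) {
  G <- as.matrix(features)
  n <- nrow(G); p <- ncol(G)
  if (length(group_codes) != n) stop("one group code per map is required")
  if (!all(group_codes %in% c(-1, 1, 0))) stop("group codes must be +/-1 (or 0)")
  if (!length(coef$beta) %in% c(1L, p) || !length(coef$gamma) %in% c(1L, p)) {
    stop("`beta`/`gamma` must be scalar or match the feature dimension (", p, ")")
  }
  beta <- rep_len(coef$beta, p)
  gamma <- rep_len(coef$gamma, p)
  set.seed(seed)
  as.numeric(coef$beta0 + G %*% beta + (group_codes * G) %*% gamma +
               stats::rnorm(n, 0, noise_sd))
}

#' Generate a full synthetic cohort
#'
#' Draws a zebrin geometry and a connectivity map per specimen across all
#' configured conditions, computes each map's absolute bilateral graph
#' feature vector, and generates a behavioural feature per map from the
#' planted GLM. With the default configuration this yields the study's
#' 105 high-resolution maps across 7 condition groups.
#'
#' @param config a [cohort_config()].
#' @param compute_features if `FALSE`, skip graph features and behaviour
#'   (faster when only maps are needed).
#' @return object of class `cohort`: list with `maps` (list of
#'   [connectivity_map()]s), `labels` (condition factor), `features`
#'   (maps x 7 matrix of absolute bilateral graph features, when
#'   computed), `behavior` (data.frame), `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            compute_features = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  conds <- config$conditions
  maps <- list(); labels <- character(0); codes <- numeric(0)
  idx <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (k in seq_len(conds$n_maps[ci])) {
      idx <- idx + 1L
      gseed <- config$seed + 1000L + idx
      geometry <- generate_zebrin_geometry(seed = gseed)
      m <- generate_map(conds$condition[ci], geometry, config,
                        seed = config$seed + 2000L + idx)
      m$map_id <- sprintf("map%03d_%s", idx, conds$condition[ci])
      m$subject_id <- sprintf("subj%03d", idx)
      maps[[idx]] <- m
      labels <- c(labels, conds$condition[ci])
      codes <- c(codes, conds$group_code[ci])
    }
  }
  features <- NULL; behavior <- NULL
  if (compute_features) {
    features <- t(vapply(seq_along(maps), function(i) {
      g <- build_correlation_graph(maps[[i]])
      p <- detect_modules(g, seed = config$seed + 3000L + i)
      assemble_features(g, p, scheme = "g_bilateral")
    }, numeric(7)))
    rownames(features) <- vapply(maps, function(m) m$map_id, character(1))
    Gimp <- features
    for (j in seq_len(ncol(Gimp))) {   # planted model acts on complete data
      Gimp[!is.finite(Gimp[, j]), j] <- stats::median(Gimp[, j], na.rm = TRUE)
    }
    y <- generate_behavior(Gimp, config$glm_coef, codes,
                           noise_sd = config$behavior_noise_sd,
                           seed = config$seed + 4000L)
    behavior <- data.frame(
      map_id = rownames(features),
      subject_id = vapply(maps, function(m) m$subject_id, character(1)),
      condition = labels, group_code = codes, y = y,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(maps = maps, labels = factor(labels, levels = conds$condition),
         group_codes = codes, features = features, behavior = behavior,
         config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$maps), "maps,",
      nlevels(x$labels), "conditions at", x$config$resolution, "um\n")
  print(table(x$labels))
  invisible(x)
}
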