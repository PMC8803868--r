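# Behavioural readouts: balance index from the force-sensor corridor and
# wheel-training metrics.

#' Session balance index from corridor trials
#'
#' Each corridor crossing yields the integrated force signals from the
#' left and right side of the body; the trial balance index is
#' BI = log10(left / right) so that 0 is perfect balance and +1 means a
#' ten-fold left bias. Trials with fewer than `min_strides` consecutive
#' strides or a non-positive integral are discarded; a session needs at
#' least `min_trials` valid trials, otherwise the datapoint is missing.
#'
#' @param trials data.frame with columns `left`, `right` (integrated
#'   force, arbitrary units) and optionally `strides`.
#' @param min_trials minimum valid trials per session (default 3).
#' @param min_strides minimum strides per trial (default 5).
#' @return list with `bi` (session mean, `NA` when too few trials),
#'   `trial_bi`, `n_valid`.
#' @export
balance_index <- function(trials, min_trials = 3, min_strides = 5) {
  stopifnot(is.data.frame(trials), all(c("left", "right") %in% names(trials)))
  valid <- is.finite(trials$left) & is.finite(trials$right) &
    trials$left > 0 & trials$right > 0
  if ("strides" %in% names(trials)) {
    valid <- valid & trials$strides >= min_strides
  }
  trial_bi <- log10(trials$left[valid] / trials$right[valid])
  list(
    bi = if (sum(valid) < min_trials) NA_real_ else mean(trial_bi),
    trial_bi = trial_bi,
    n_valid = sum(valid)
  )
}

# trapezoidal integral of the time course restricted to [from, to], with
# linear interpolation at the window ends so adjacent windows tile exactly
.window_auc <- function(day, value, from, to) {
  to <- min(to, max(day))
  from <- max(from, min(day))
  if (from >= to) stop("phase window [", from, ", ", to, ") is empty")
  inside <- day > from & day < to
  xs <- c(from, day[inside], to)
  ys <- stats::approx(day, value, xout = xs)$y
  pracma::trapz(xs, ys)
}

#' Balance-index time-course features
#'
#' Normalises a post-surgery balance-index time course to its pre-surgery
#' baseline (subtraction) and summarises it: cumulative imbalance (area
#' under the curve, trapezoidal) over the early, late and adapted phases,
#' and the maximum-imbalance readout BI_day15, the measurement nearest
#' day 15. Phase windows default to 0-9 / 9-21 / 21-end days
#' post-surgery; the alternative late window 4-21 used for some analyses
#' can be set through `phases`.
#'
#' @param day numeric vector of measurement days (post-surgery, strictly
#'   increasing).
#' @param bi balance index at each day.
#' @param baseline pre-surgery balance index (subtracted).
#' @param phases named list of `c(start, end)` windows in days.
#' @param day_peak day of the maximum-imbalance readout (default 15).
#' @return list with `bi_day15`, `auc_early`, `auc_late`, `auc_adapted`,
#'   and the normalised `timecourse` data.frame.
#' @export
bi_features <- function(day, bi, baseline = 0,
                        phases = list(early = c(0, 9), late = c(9, 21),
                                      adapted = c(21, Inf)),
                        day_peak = 15) {
  stopifnot(length(day) == length(bi), all(diff(day) > 0))
  v <- bi - baseline
  feats <- lapply(phases, function(w) .window_auc(day, v, w[1], w[2]))
  list(
    bi_day15 = v[which.min(abs(day - day_peak))],
    auc_early = feats$early,
    auc_late = feats$late,
    auc_adapted = feats$adapted,
    timecourse = data.frame(day = day, bi = v)
  )
}

#' Wheel-training metrics
#'
#' Total distance run over all sessions and the slope of the training
#' trajectory, the ordinary-least-squares slope of distance against
#' session index (m/session).
#'
#' @param distance distance per session (m).
#' @param session session indices (default 1, 2, ...).
#' @return list with `total_distance`, `slope`, and the fitted `lm`.
#' @export
wheel_metrics <- function(distance, session = seq_along(distance)) {
  if (length(distance) < 2L) stop("need >= 2 sessions")
  fit <- stats::lm(distance ~ session)
  list(
    total_distance = sum(distance),
    slope = unname(stats::coef(fit)[2]),
    fit = fit
  )
}

#' Logistic fit of a group training trajectory
#'
#' Convenience display fit of mean distance against session with a
#' self-starting logistic curve; returns `NULL` invisibly when the fit
#' fails to converge.
#'
#' @param distance,session as in [wheel_metrics()].
#' @return an `nls` fit or `NULL`.
#' @export
wheel_logistic_fit <- function(distance, session = seq_along(distance)) {
  fit <- try(stats::nls(distance ~ SSlogis(session, Asym, xmid, scal)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(invisible(NULL))
  fit
}
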