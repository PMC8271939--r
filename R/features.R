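#' Smooth a heart-rate series with a trailing moving average
#'
#' Each output value is the mean of the input samples with timestamps in the
#' half-open window `(t - window_s, t]`. The window shrinks at the start of
#' the series (no padding), output timestamps are unchanged, and a window
#' shorter than the sampling interval leaves the series untouched. The
#' trailing (causal) form means the smoother could run in real time on a
#' wearable stream.
#'
#' @param hr A heart-rate [sensor_series()].
#' @param window_s Window length in seconds (default 4).
#' @return A [sensor_series()] of the same length and time base.
#' @examples
#' s <- sensor_series(0:3, c(100, 104, 108, 112), 1, "bpm")
#' smooth_hr(s)$values[4]  # mean of all four samples = 106
#' @export
smooth_hr <- function(hr, window_s = 4) {
  if (!inherits(hr, "sensor_series")) {
    stop("smooth_hr: 'hr' must be a sensor_series", call. = FALSE)
  }
  if (window_s <= 0) stop("smooth_hr: 'window_s' must be positive", call. = FALSE)
  t <- hr$time
  cs <- c(0, cumsum(hr$values))
  # exclude samples with time <= t_i - window_s
  k <- findInterval(t - window_s, t)
  i <- seq_along(t)
  sm <- (cs[i + 1L] - cs[k + 1L]) / (i - k)
  sensor_series(t, sm, nominal_rate = hr$nominal_rate, units = hr$units)
}

# symmetric moving average over (t - half, t + half], used as the
# transition-detection prefilter (non-causal, detection only)
centered_ma <- function(t, v, width_s) {
  cs <- c(0, cumsum(v))
  lo <- findInterval(t - width_s / 2, t)            # samples <= t - half excluded
  hi <- findInterval(t + width_s / 2, t)            # samples <= t + half included
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect a postural transition from trunk-pitch velocity
#'
#' Low-pass filters the pitch trace (moving average, `prefilter_s` seconds),
#' differentiates it by central finite differences, and returns the
#' timestamp of maximum absolute pitch velocity within the search window,
#' which should bracket exactly one scripted posture-to-stand change. Ties
#' are broken toward the earliest sample. If the peak velocity magnitude is
#' below `velocity_floor` the window is judged to contain no transition and
#' an error of class `hydrostatus_no_transition` is thrown.
#'
#' @param pitch A trunk-pitch [sensor_series()].
#' @param search_window Numeric `c(t_a, t_b)`: half-open window `[t_a, t_b)`
#'   in seconds, inside the series span.
#' @param prefilter_s Moving-average prefilter width in seconds (default 0.5).
#' @param velocity_floor Minimum credible peak speed in deg/s (default 5).
#' @return The detected transition time in seconds.
#' @export
detect_transition <- function(pitch, search_window, prefilter_s = 0.5,
                              velocity_floor = 5) {
  if (!inherits(pitch, "sensor_series")) {
    stop("detect_transition: 'pitch' must be a sensor_series", call. = FALSE)
  }
  if (length(search_window) != 2L || search_window[1L] >= search_window[2L]) {
    stop("detect_transition: malformed search window", call. = FALSE)
  }
  sp <- series_span(pitch)
  if (search_window[1L] < sp[1L] || search_window[2L] > sp[2L] + 1 / pitch$nominal_rate) {
    stop("detect_transition: search window outside the series span", call. = FALSE)
  }
  # work on the window plus enough margin for the prefilter and differences
  margin <- prefilter_s + 2 / pitch$nominal_rate
  keep <- pitch$time >= search_window[1L] - margin &
    pitch$time < search_window[2L] + margin
  t <- pitch$time[keep]; v <- pitch$values[keep]
  if (length(t) < 3L) {
    stop("detect_transition: too few samples in the search window", call. = FALSE)
  }
  f <- centered_ma(t, v, prefilter_s)
  n <- length(t)
  mid <- 2:(n - 1L)
  vel <- (f[mid + 1L] - f[mid - 1L]) / (t[mid + 1L] - t[mid - 1L])
  tm <- t[mid]
  in_win <- tm >= search_window[1L] & tm < search_window[2L]
  if (!any(in_win)) {
    stop("detect_transition: no interior samples in the search window", call. = FALSE)
  }
  speed <- abs(vel[in_win])
  tw <- tm[in_win]
  peak <- max(speed)
  if (peak < velocity_floor) {
    stop(errorCondition(
      sprintf("detect_transition: peak |pitch velocity| %.3g deg/s below floor %.3g",
              peak, velocity_floor),
      class = c("hydrostatus_no_transition", "error", "condition")))
  }
  tw[which(speed == peak)[1L]] # earliest among ties
}

#' Extract baseline-relative segmented heart-rate features
#'
#' The post-transition standing period of length `post_duration` is split
#' into three equal segments; the feature vector is the difference between
#' each segment's mean smoothed heart rate and the mean over the 10 s
#' immediately preceding the transition. Sample-inclusion intervals are
#' half-open: pre-window `[t - pre_window_s, t)`, segment i
#' `[t + (i-1) L/3, t + i L/3)` with `L = post_duration`. Referencing every
#' segment to the local pre-transition baseline removes between-person
#' resting heart-rate differences and slow exercise-recovery drift.
#'
#' @param hr_smoothed A smoothed heart-rate [sensor_series()] (see
#'   [smooth_hr()]).
#' @param transition_time Transition time in seconds.
#' @param post_duration Standing duration `L` in seconds (30 or 60 in the
#'   scripted battery).
#' @param pre_window_s Pre-transition baseline window in seconds (default 10).
#' @return Named numeric vector `c(d1, d2, d3)` in bpm.
#' @examples
#' hr <- sensor_series(0:49, c(rep(100, 20), rep(120, 30)), 1, "bpm")
#' extract_features(hr, transition_time = 20, post_duration = 30)
#' @export
extract_features <- function(hr_smoothed, transition_time, post_duration,
                             pre_window_s = 10) {
  if (!inherits(hr_smoothed, "sensor_series")) {
    stop("extract_features: 'hr_smoothed' must be a sensor_series", call. = FALSE)
  }
  if (post_duration <= 0) {
    stop("extract_features: 'post_duration' must be positive", call. = FALSE)
  }
  tt <- transition_time
  seg <- post_duration / 3
  windows <- list(pre = c(tt - pre_window_s, tt),
                  s1 = c(tt, tt + seg),
                  s2 = c(tt + seg, tt + 2 * seg),
                  s3 = c(tt + 2 * seg, tt + 3 * seg))
  means <- vapply(windows, function(w) {
    v <- window_values(hr_smoothed, w[1L], w[2L])
    if (length(v) < 2L) {
      stop(sprintf(
        "extract_features: fewer than 2 samples in window [%.3f, %.3f)",
        w[1L], w[2L]), call. = FALSE)
    }
    mean(v)
  }, numeric(1))
  c(d1 = means[["s1"]] - means[["pre"]],
    d2 = means[["s2"]] - means[["pre"]],
    d3 = means[["s3"]] - means[["pre"]])
}

#' Extract the labeled feature rows of one session
#'
#' Runs the full per-repetition pipeline on a session: smooth the heart
#' rate, detect each repetition's transition from pitch velocity within a
#' window around the scripted time, extract the three baseline-relative
#' features, and attach the hydration label implied by the crossover design
#' (dehydrated iff post-exercise in the no-fluid session).
#'
#' @param session A [sensor_session()].
#' @param smooth_window_s Heart-rate smoothing window (s).
#' @param search_halfwidth Half-width of the transition search window around
#'   the scripted transition time (s).
#' @param prefilter_s,velocity_floor Passed to [detect_transition()].
#' @return A data.frame with one row per repetition: identifiers, detected
#'   `transition_time`, features `d1`, `d2`, `d3`, and `label`.
#' @export
extract_session_features <- function(session, smooth_window_s = 4,
                                     search_halfwidth = 5,
                                     prefilter_s = 0.5, velocity_floor = 5) {
  stopifnot(inherits(session, "sensor_session"))
  hr_s <- smooth_hr(session$hr, smooth_window_s)
  sched <- session$schedule
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    t0 <- sched$transition_time[i]
    t_hat <- detect_transition(session$pitch,
                               c(t0 - search_halfwidth, t0 + search_halfwidth),
                               prefilter_s = prefilter_s,
                               velocity_floor = velocity_floor)
    fv <- extract_features(hr_s, t_hat, post_duration = sched$phase2_duration[i])
    rows[[i]] <- data.frame(
      participant_id = session$participant_id,
      session_type = session$session_type,
      timing = session$timing,
      movement_type = sched$movement_type[i],
      repetition = sched$repetition[i],
      transition_time = t_hat,
      d1 = fv[["d1"]], d2 = fv[["d2"]], d3 = fv[["d3"]],
      label = hydration_label(session$session_type, session$timing),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Build the labeled feature dataset of a study
#'
#' Applies [extract_session_features()] to every session and stacks the
#' rows. Every scheduled repetition must yield a feature vector (a failed
#' extraction is an error, never a silent drop); labels are a pure function
#' of (session type, timing). A full two-session participant contributes 48
#' rows, 12 of them dehydrated; filtering to post-exercise leaves 24.
#'
#' @param sessions A list of [sensor_session()] objects, or a
#'   `synthetic_study`.
#' @param ... Passed to [extract_session_features()].
#' @return A data.frame of class `hyd_dataset`.
#' @examples
#' \donttest{
#' study <- simulate_cohort(3, seed = 1)
#' ds <- build_labeled_dataset(study)
#' table(ds$label)
#' }
#' @export
build_labeled_dataset <- function(sessions, ...) {
  if (inherits(sessions, "synthetic_study")) sessions <- sessions$sessions
  if (!is.list(sessions) || length(sessions) == 0L ||
      !all(vapply(sessions, inherits, logical(1), "sensor_session"))) {
    stop("build_labeled_dataset: 'sessions' must be a non-empty list of sensor_session objects",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(sessions, extract_session_features, ...))
  expected <- sum(vapply(sessions, function(s) nrow(s$schedule), integer(1)))
  if (nrow(out) != expected) {
    stop("build_labeled_dataset: some repetitions lack a feature vector", call. = FALSE)
  }
  class(out) <- c("hyd_dataset", "data.frame")
  out
}

#' Aligned average heart-rate response by hydration state
#'
#' Resamples each repetition's smoothed heart rate onto a common grid
#' relative to its transition, averages pointwise within each label group,
#' and shifts each mean curve so its value at the transition sample is zero,
#' so post-transition trajectories can be compared across states. The
#' pointwise standard error of each group is returned.
#'
#' @param reps A list of repetitions, each a list with elements
#'   `hr_smoothed` (a [sensor_series()]), `transition_time` and `label`.
#' @param pre_s,post_s Grid extent before/after the transition (s).
#' @param step_s Grid spacing (s).
#' @return An object of class `aligned_response`: list with `time` (seconds
#'   relative to transition), `mean` and `se` (matrices, one column per
#'   label), and `n` per label.
#' @export
aligned_average_response <- function(reps, pre_s = 10, post_s = 30, step_s = 1) {
  if (length(reps) == 0L) stop("aligned_average_response: no repetitions", call. = FALSE)
  labels <- vapply(reps, function(r) as.character(r$label), character(1))
  grid <- seq(-pre_s, post_s, by = step_s)
  if (!any(grid == 0)) stop("aligned_average_response: grid must contain 0", call. = FALSE)
  curves <- vapply(reps, function(r) {
    s <- r$hr_smoothed
    stats::approx(s$time - r$transition_time, s$values, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  if (anyNA(curves)) {
    stop("aligned_average_response: a repetition does not cover the grid", call. = FALSE)
  }
  groups <- unique(labels)
  mean_mat <- matrix(NA_real_, length(grid), length(groups),
                     dimnames = list(NULL, groups))
  se_mat <- mean_mat
  n_by <- stats::setNames(integer(length(groups)), groups)
  i0 <- which(grid == 0)
  for (g in groups) {
    cg <- curves[, labels == g, drop = FALSE]
    if (ncol(cg) == 0L) stop("aligned_average_response: empty label group", call. = FALSE)
    m <- rowMeans(cg)
    mean_mat[, g] <- m - m[i0]
    se_mat[, g] <- if (ncol(cg) > 1L) apply(cg, 1L, stats::sd) / sqrt(ncol(cg)) else 0
    n_by[g] <- ncol(cg)
  }
  structure(list(time = grid, mean = mean_mat, se = se_mat, n = n_by),
            class = "aligned_response")
}

#' @export
print.aligned_response <- function(x, ...) {
  cat(sprintf("<aligned_response> grid %g..%g s, groups: %s\n",
              min(x$time), max(x$time),
              paste(sprintf("%s (n=%d)", colnames(x$mean), x$n), collapse = ", ")))
  invisible(x)
}

#' Plot an aligned average heart-rate response
#'
#' @param x An `aligned_response` from [aligned_average_response()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.aligned_response <- function(x, ...) {
  graphics::matplot(x$time, x$mean, type = "l", lty = 1, lwd = 2,
                    xlab = "Time from transition (s)",
                    ylab = "Heart rate relative to transition (bpm)", ...)
  for (j in seq_len(ncol(x$mean))) {
    graphics::lines(x$time, x$mean[, j] + x$se[, j], lty = 3, col = j)
    graphics::lines(x$time, x$mean[, j] - x$se[, j], lty = 3, col = j)
  }
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = colnames(x$mean), lty = 1, lwd = 2,
                   col = seq_len(ncol(x$mean)), bty = "n")
  invisible(x)
}
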