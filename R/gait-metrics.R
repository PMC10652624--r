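#' Step detection configuration
#'
#' Steps are identified as peaks of a smoothed gyroscope axis: each foot
#' strike produces a burst of shank angular velocity.
#'
#' @param min_peak_height minimum peak angular velocity, deg/s.
#' @param min_inter_peak_interval minimum time between successive peaks, s
#'   (default 0.25 s, i.e. a cadence cap of 240 steps/min).
#' @param smoothing_halfwidth half-width of the centred moving-average
#'   smoother, samples (0 disables smoothing).
#' @param axis `"auto"` picks the gyro axis with the largest variance;
#'   otherwise one of `"gx"`, `"gy"`, `"gz"`.
#' @return A list of class `step_config`.
#' @export
step_config <- function(min_peak_height = 50, min_inter_peak_interval = 0.25,
                        smoothing_halfwidth = 5L, axis = "auto") {
  stopifnot(min_inter_peak_interval > 0, smoothing_halfwidth >= 0)
  structure(list(min_peak_height = min_peak_height,
                 min_inter_peak_interval = min_inter_peak_interval,
                 smoothing_halfwidth = as.integer(smoothing_halfwidth),
                 axis = axis),
            class = "step_config")
}

#' Detect foot strikes from gyroscope data
#'
#' Applies a centred moving average to the selected gyro axis and finds
#' peaks above `min_peak_height` separated by at least
#' `min_inter_peak_interval`.
#'
#' @param recording an [imu_recording()] with gyro channels.
#' @param config a [step_config()].
#' @return Numeric vector of step times (time of each peak sample), s.
#' @export
detect_steps <- function(recording, config = step_config()) {
  if (is.null(recording$gyro)) {
    stop("no gyroscope channels in recording", call. = FALSE)
  }
  g <- if (config$axis == "auto") {
    recording$gyro[, which.max(apply(recording$gyro, 2, stats::var))]
  } else {
    recording$gyro[, config$axis]
  }
  h <- config$smoothing_halfwidth
  if (h > 0) {
    k <- 2L * h + 1L
    g <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
    g[is.na(g)] <- 0
  }
  fs <- recording$sampling_rate
  pk <- pracma::findpeaks(g, minpeakheight = config$min_peak_height,
                          minpeakdistance = max(1L, round(config$min_inter_peak_interval * fs)))
  if (is.null(pk)) return(numeric(0))
  sort(recording$time[pk[, 2]])
}

#' Step frequency in steps per minute
#'
#' Total detected (or annotated) foot strikes averaged over the duration:
#' `count / duration * 60`. Event logs contribute strikes from both sides.
#'
#' @param x numeric step times, or a [gait_event_log()].
#' @param duration segment duration, s (> 0).
#' @return Steps per minute.
#' @export
step_frequency <- function(x, duration) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n <- if (inherits(x, "gait_event_log")) length(strike_times(x)) else length(x)
  n / duration * 60
}

#' Step symmetry index from sided foot strikes
#'
#' A step interval is the time from one strike to the next opposite-side
#' strike, classified by its initiating side. The index is
#' `|mean(left-initiated) - mean(right-initiated)| / mean(all intervals)`:
#' dimensionless, and exactly 0 for perfectly alternating equal intervals.
#'
#' @param log a [gait_event_log()] with at least 2 strikes per side.
#' @return Symmetry index (>= 0), or `NA` with a warning when a side has
#'   fewer than 2 strikes.
#' @export
symmetry_index <- function(log) {
  st <- log[log$type %in% c("strike_left", "strike_right"), , drop = FALSE]
  if (sum(st$side == "left") < 2 || sum(st$side == "right") < 2) {
    warning("symmetry index undefined: fewer than 2 strikes on a side")
    return(NA_real_)
  }
  dt <- diff(st$time)
  init <- st$side[-nrow(st)]
  nxt <- st$side[-1]
  alt <- init != nxt  # only intervals between opposite-side strikes
  if (!any(alt & init == "left") || !any(alt & init == "right")) {
    warning("symmetry index undefined: no alternating intervals on a side")
    return(NA_real_)
  }
  li <- mean(dt[alt & init == "left"])
  ri <- mean(dt[alt & init == "right"])
  abs(li - ri) / mean(dt[alt])
}

#' Stride lengths by drift-corrected double integration
#'
#' For each gait cycle — the span between two consecutive same-side foot
#' strikes — the horizontal acceleration is integrated twice (trapezoid
#' rule) with a zero-velocity update at each cycle boundary: the velocity is
#' anchored to zero at the cycle start and the linear velocity trend implied
#' by the (should-be-zero) end velocity is subtracted before the second
#' integration. A constant accelerometer bias produces a purely linear
#' velocity drift and is therefore removed exactly.
#'
#' @param recording an [imu_recording()].
#' @param step_times either the `step_times` list (`left`/`right`) from the
#'   generator truth — the left strikes then delimit cycles — or a numeric
#'   vector of same-side strike times, or a numeric vector of alternating
#'   strikes (odd entries are taken as cycle boundaries when
#'   `alternating = TRUE`).
#' @param axis horizontal acceleration channel (default `"ax"`, the forward
#'   axis of the synthetic generator). `"auto"` subtracts a 0.1 Hz low-pass
#'   gravity estimate and picks the dominant remaining axis — a heuristic
#'   for real recordings where the forward axis is unknown.
#' @param alternating treat a numeric `step_times` vector as alternating
#'   left/right strikes.
#' @return Numeric vector of per-cycle stride lengths, m (empty, with a
#'   warning, when fewer than one full cycle is available).
#' @export
stride_lengths <- function(recording, step_times, axis = "ax",
                           alternating = FALSE) {
  if (is.list(step_times)) {
    boundaries <- sort(step_times$left)
  } else if (alternating) {
    boundaries <- sort(step_times)[c(TRUE, FALSE)]
  } else {
    boundaries <- sort(step_times)
  }
  if (length(boundaries) < 2) {
    warning("fewer than one full gait cycle; no stride lengths")
    return(numeric(0))
  }
  a <- horizontal_acceleration(recording, axis)
  t <- recording$time
  vapply(seq_len(length(boundaries) - 1L), function(i) {
    idx <- which(t >= boundaries[i] & t <= boundaries[i + 1L])
    if (length(idx) < 3) return(NA_real_)
    tt <- t[idx]
    v <- pracma::cumtrapz(tt, a[idx])[, 1]
    # ZUPT: v(start) = 0 by construction; remove the linear drift that makes
    # v(end) nonzero
    v <- v - (tt - tt[1]) / (tt[length(tt)] - tt[1]) * v[length(v)]
    x <- pracma::cumtrapz(tt, v)[, 1]
    abs(x[length(x)])
  }, numeric(1))
}

horizontal_acceleration <- function(recording, axis) {
  if (axis %in% c("ax", "ay", "az")) {
    return(recording$accel[, axis])
  }
  if (axis != "auto") stop("axis must be one of ax, ay, az, auto", call. = FALSE)
  fs <- recording$sampling_rate
  bf <- signal::butter(2, 0.1 / (fs / 2), type = "low")
  dyn <- apply(recording$accel, 2, function(col) {
    col - signal::filtfilt(bf, col)
  })
  dyn[, which.max(apply(dyn, 2, stats::var))]
}

#' Freeze metrics over a completion window
#'
#' Counts freeze episodes, their cumulative duration, and that duration as a
#' percentage of the completion time. Input is either an annotated event log
#' (freeze_start/freeze_end pairs) or a `fog_track` of window predictions,
#' which is first merged into episodes: consecutive FOG windows are joined,
#' tolerating up to `gap_tolerance` non-FOG windows inside an episode.
#'
#' @param x a [gait_event_log()] or a `fog_track` from [fog_predict()].
#' @param completion_window `c(start, end)` of the circuit/segment, s.
#' @param gap_tolerance number of consecutive non-FOG windows tolerated
#'   inside a merged episode (prediction tracks only).
#' @return List `freeze_count`, `cumulative_freeze_time` (s),
#'   `freeze_time_fraction` (% of completion time), `intervals`.
#' @export
freeze_metrics <- function(x, completion_window, gap_tolerance = 1L) {
  stopifnot(length(completion_window) == 2, completion_window[2] > completion_window[1])
  iv <- if (inherits(x, "gait_event_log")) freeze_intervals(x)
        else merge_fog_windows(x, gap_tolerance)
  if (nrow(iv)) {
    clipped <- pmax(iv$start, completion_window[1])
    clipped_end <- pmin(iv$end, completion_window[2])
    if (any(iv$start < completion_window[1] | iv$end > completion_window[2])) {
      warning("freeze interval extends outside the completion window; clipped")
    }
    keep <- clipped_end > clipped
    iv <- data.frame(start = clipped[keep], end = clipped_end[keep])
  }
  total <- if (nrow(iv)) sum(iv$end - iv$start) else 0
  span <- completion_window[2] - completion_window[1]
  list(freeze_count = nrow(iv),
       cumulative_freeze_time = total,
       freeze_time_fraction = 100 * total / span,
       intervals = iv)
}

# Merge consecutive FOG-labeled windows of a prediction track into episode
# intervals. Window i covers (t_i - window_span, t_i]; its span is inferred
# from the track spacing.
merge_fog_windows <- function(track, gap_tolerance = 1L) {
  fog <- track$label_pred == "fog"
  if (!any(fog)) return(data.frame(start = numeric(0), end = numeric(0)))
  t <- track$window_end_time
  hop <- if (length(t) > 1) stats::median(diff(t)) else 0
  idx <- which(fog)
  brk <- which(diff(idx) > gap_tolerance + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  data.frame(start = t[starts] - hop, end = t[ends])
}

#' Between-observer percentage coefficient of variation
#'
#' For each trial (row), 100 * sd / mean across the observers' scores; the
#' returned %CV is the average over trials. Used to quantify agreement of
#' independent video annotators on a gait metric.
#'
#' @param scores numeric matrix or data frame, trials in rows, observers in
#'   columns (>= 2); a plain vector is treated as one trial.
#' @return Mean %CV across trials (`NA` with a warning for a zero-mean
#'   trial).
#' @export
observer_cv <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("observer_cv needs >= 2 observers", call. = FALSE)
  cv <- apply(scores, 1, function(row) {
    m <- mean(row)
    if (m == 0) {
      warning("zero mean score; %CV undefined for a trial")
      return(NA_real_)
    }
    100 * stats::sd(row) / m
  })
  mean(cv)
}

#' Summarise a trial into the study gait metrics
#'
#' Assembles the per-circuit metric panel from an event log (and optionally
#' an IMU recording for IMU-derived stride lengths): step count and
#' frequency, symmetry index, freeze count / cumulative freeze time /
#' freeze-time fraction, and completion time.
#'
#' @param log a [gait_event_log()].
#' @param completion_window `c(start, end)`, s; default spans the log.
#' @param recording optional [imu_recording()] for stride lengths.
#' @param stride_axis horizontal axis passed to [stride_lengths()].
#' @return A list of class `gait_summary`.
#' @export
gait_summary <- function(log, completion_window = NULL, recording = NULL,
                         stride_axis = "ax") {
  if (is.null(completion_window)) {
    completion_window <- range(log$time)
  }
  dur <- completion_window[2] - completion_window[1]
  steps <- strike_times(log)
  fm <- freeze_metrics(log, completion_window)
  strides <- if (!is.null(recording)) {
    stride_lengths(recording,
                   list(left = strike_times(log, "left"),
                        right = strike_times(log, "right")),
                   axis = stride_axis)
  } else numeric(0)
  structure(list(step_count = length(steps),
                 step_frequency = step_frequency(steps, dur),
                 symmetry_index = suppressWarnings(symmetry_index(log)),
                 stride_lengths = strides,
                 mean_stride_length = if (length(strides)) mean(strides, na.rm = TRUE) else NA_real_,
                 freeze_count = fm$freeze_count,
                 cumulative_freeze_time = fm$cumulative_freeze_time,
                 freeze_time_fraction = fm$freeze_time_fraction,
                 completion_time = dur),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat("<gait_summary>\n")
  cat(sprintf("  steps: %d (%.1f steps/min), symmetry index %.3f\n",
              x$step_count, x$step_frequency, x$symmetry_index))
  if (length(x$stride_lengths)) {
    cat(sprintf("  mean stride length: %.2f m over %d cycles\n",
                x$mean_stride_length, length(x$stride_lengths)))
  }
  cat(sprintf("  freezes: %d, %.1f s total (%.1f%% of %.1f s)\n",
              x$freeze_count, x$cumulative_freeze_time,
              x$freeze_time_fraction, x$completion_time))
  invisible(x)
}
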