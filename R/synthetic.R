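#' Configuration for the synthetic gait generator
#'
#' Parameterizes the statistical structure the FOG detection framework
#' assumes in lower-leg IMU data: a locomotor oscillation whose power is
#' concentrated in the walking band (0.5-3 Hz), FOG episodes that are either
#' trembling (3-8 Hz shank oscillation) or akinetic (near-zero movement),
#' periodic gyroscope peaks at foot strikes, and additive sensor noise.
#'
#' Defaults describe a moderately impaired walker on a 100 Hz sensor, so a
#' 256-sample analysis window spans about 2.5 s of data.
#'
#' @param sampling_rate Hz; must exceed 16 Hz so the 8 Hz freeze-band edge is
#'   below Nyquist.
#' @param duration recording length, s.
#' @param step_frequency steps/min; the locomotor fundamental is
#'   `step_frequency/60` Hz and must fall in the 0.5-3 Hz walking band.
#' @param stride_length_mean,stride_length_sd per-gait-cycle stride length
#'   distribution, m.
#' @param walk_band_amplitude amplitude of the locomotor fundamental, m/s^2.
#'   Two harmonics with geometrically decaying amplitude (`harmonic_decay`)
#'   are added on top.
#' @param harmonic_decay amplitude ratio between successive harmonics.
#' @param freeze_tremble_frequency centre of the per-episode trembling
#'   frequency, Hz; must lie in the 3-8 Hz freeze band.
#' @param freeze_tremble_amplitude trembling oscillation amplitude, m/s^2.
#' @param fog_episode_rate FOG episode onsets per minute of walking
#'   (Poisson renewal process).
#' @param fog_duration_mean,fog_duration_sd log-normal episode duration
#'   moments, s.
#' @param fog_mode_mix fraction of episodes that are trembling rather than
#'   akinetic, in `[0, 1]`. Both modes are labeled `fog`.
#' @param noise_sd accelerometer noise standard deviation, m/s^2.
#' @param gyro_peak_amplitude peak shank angular velocity at a foot strike,
#'   deg/s.
#' @param gravity_offset constant offset added to the z accelerometer axis,
#'   m/s^2 (default 0; feature extraction is band-limited above 0.5 Hz so
#'   this cannot change the freeze index).
#' @param seed integer; identical seeds yield bit-identical recordings.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(sampling_rate = 100, duration = 600,
                             step_frequency = 100,
                             stride_length_mean = 1.2, stride_length_sd = 0.1,
                             walk_band_amplitude = 2.0, harmonic_decay = 0.25,
                             freeze_tremble_frequency = 5,
                             freeze_tremble_amplitude = 1.5,
                             fog_episode_rate = 2,
                             fog_duration_mean = 8, fog_duration_sd = 4,
                             fog_mode_mix = 0.7,
                             noise_sd = 0.3, gyro_peak_amplitude = 200,
                             gravity_offset = 0, seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              step_frequency = step_frequency,
              stride_length_mean = stride_length_mean,
              stride_length_sd = stride_length_sd,
              walk_band_amplitude = walk_band_amplitude,
              harmonic_decay = harmonic_decay,
              freeze_tremble_frequency = freeze_tremble_frequency,
              freeze_tremble_amplitude = freeze_tremble_amplitude,
              fog_episode_rate = fog_episode_rate,
              fog_duration_mean = fog_duration_mean,
              fog_duration_sd = fog_duration_sd,
              fog_mode_mix = fog_mode_mix, noise_sd = noise_sd,
              gyro_peak_amplitude = gyro_peak_amplitude,
              gravity_offset = gravity_offset, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) stop("invalid synthetic_config: ", msg, call. = FALSE)
  if (cfg$sampling_rate <= 16) {
    fail("sampling_rate must exceed 16 Hz (twice the 8 Hz freeze-band edge)")
  }
  if (cfg$freeze_tremble_frequency < 3 || cfg$freeze_tremble_frequency > 8) {
    fail("freeze_tremble_frequency must lie in the 3-8 Hz freeze band")
  }
  f0 <- cfg$step_frequency / 60
  if (f0 < 0.5 || f0 > 3) {
    fail("step_frequency/60 must lie in the 0.5-3 Hz walking band")
  }
  nonneg <- c("duration", "stride_length_mean", "stride_length_sd",
              "walk_band_amplitude", "freeze_tremble_amplitude",
              "fog_episode_rate", "fog_duration_mean", "fog_duration_sd",
              "noise_sd", "gyro_peak_amplitude")
  for (f in nonneg) if (cfg[[f]] < 0) fail(paste(f, "must be >= 0"))
  if (cfg$fog_mode_mix < 0 || cfg$fog_mode_mix > 1) {
    fail("fog_mode_mix must be in [0, 1]")
  }
  invisible(cfg)
}

# Run expr under a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Lay out alternating walking bouts and FOG episodes over [0, duration].
# Episode onsets form a Poisson process on walking time (rate per minute of
# walking); durations are log-normal with the configured mean/sd.
draw_episodes <- function(cfg) {
  if (cfg$fog_episode_rate == 0 || cfg$duration == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  rate_s <- cfg$fog_episode_rate / 60
  cv2 <- (cfg$fog_duration_sd / cfg$fog_duration_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(cfg$fog_duration_mean) - sdlog^2 / 2
  start <- end <- numeric(0)
  mode <- character(0)
  t <- 0
  repeat {
    gap <- stats::rexp(1, rate_s)
    onset <- t + gap
    if (onset >= cfg$duration) break
    dur <- stats::rlnorm(1, meanlog, sdlog)
    fin <- min(onset + dur, cfg$duration)
    start <- c(start, onset); end <- c(end, fin)
    mode <- c(mode, if (stats::runif(1) < cfg$fog_mode_mix) "trembling" else "akinetic")
    t <- fin
    if (t >= cfg$duration) break
  }
  data.frame(start = start, end = end, mode = mode, stringsAsFactors = FALSE)
}

# Foot strikes at interval 60/step_frequency within walking intervals,
# alternating left/right across the whole recording.
place_steps <- function(cfg, episodes) {
  dt <- 60 / cfg$step_frequency
  walk <- walking_intervals(cfg$duration, episodes)
  times <- unlist(lapply(seq_len(nrow(walk)), function(i) {
    a <- walk$start[i]; b <- walk$end[i]
    if (b - a < dt) return(numeric(0))
    seq(a + dt / 2, b, by = dt)
  }))
  if (is.null(times)) times <- numeric(0)
  sides <- rep_len(c("left", "right"), length(times))
  list(times = times, sides = sides)
}

walking_intervals <- function(duration, episodes) {
  if (!nrow(episodes)) {
    return(data.frame(start = 0, end = duration))
  }
  starts <- c(0, episodes$end)
  ends <- c(episodes$start, duration)
  keep <- ends - starts > 1e-9
  data.frame(start = starts[keep], end = ends[keep])
}

#' Generate a labeled synthetic IMU recording
#'
#' Produces a recording that alternates walking bouts with FOG episodes drawn
#' from a renewal process, together with exact ground truth. Walking bouts
#' carry a locomotor acceleration at the step frequency plus two decaying
#' harmonics and periodic gyroscope peaks at each foot strike; trembling
#' episodes replace this with a 3-8 Hz oscillation; akinetic episodes have no
#' movement beyond noise. Gaussian sensor noise is added throughout.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `recording` ([imu_recording]) and `truth`, a
#'   list of class `gait_truth` with fields `fog_mask` (per-sample logical),
#'   `step_times` (list with `left`/`right` strike times; empty when the
#'   config produces no movement at all), `stride_lengths` (nominal
#'   per-cycle draws), and `episodes` (data frame `start`, `end`, `mode`).
#' @seealso [generate_trajectory()] for a recording whose acceleration is the
#'   exact second derivative of a known displacement profile.
#' @export
generate_recording <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    fs <- cfg$sampling_rate
    n <- round(cfg$duration * fs)
    time <- seq_len(n) / fs - 1 / fs

    episodes <- draw_episodes(cfg)
    fog_mask <- rep(FALSE, n)
    for (i in seq_len(nrow(episodes))) {
      fog_mask[time >= episodes$start[i] & time < episodes$end[i]] <- TRUE
    }

    steps <- place_steps(cfg, episodes)
    no_movement <- cfg$walk_band_amplitude == 0 && cfg$gyro_peak_amplitude == 0
    if (no_movement) steps <- list(times = numeric(0), sides = character(0))

    # walking oscillation: fundamental + 2 harmonics, geometric decay
    f0 <- cfg$step_frequency / 60
    axis_scale <- c(1, 0.6, 0.4)
    walk_sig <- rep(0, n)
    phases <- stats::runif(3, 0, 2 * pi)
    for (h in 1:3) {
      amp <- cfg$walk_band_amplitude * cfg$harmonic_decay^(h - 1)
      walk_sig <- walk_sig + amp * sin(2 * pi * h * f0 * time + phases[h])
    }
    walking <- !fog_mask
    accel <- sapply(axis_scale, function(s) s * walk_sig * walking)

    # trembling episodes: per-episode frequency near the configured centre
    tremble_scale <- c(1, 0.8, 0.6)
    for (i in seq_len(nrow(episodes))) {
      if (episodes$mode[i] != "trembling") next
      fi <- episodes$start[i] <= time & time < episodes$end[i]
      ft <- stats::runif(1, max(3, cfg$freeze_tremble_frequency - 1),
                         min(8, cfg$freeze_tremble_frequency + 1))
      ph <- stats::runif(1, 0, 2 * pi)
      osc <- cfg$freeze_tremble_amplitude * sin(2 * pi * ft * time[fi] + ph)
      accel[fi, ] <- accel[fi, , drop = FALSE] + outer(osc, tremble_scale)
    }

    if (cfg$noise_sd > 0) {
      accel <- accel + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd), n, 3)
    }
    accel[, 3] <- accel[, 3] + cfg$gravity_offset

    gyro <- gyro_step_pulses(time, steps$times, fs, cfg$gyro_peak_amplitude)
    if (cfg$noise_sd > 0 && cfg$gyro_peak_amplitude > 0) {
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, 0.01 * cfg$gyro_peak_amplitude), n, 3)
    }

    n_cycles <- max(0L, floor(length(steps$times) / 2))
    strides <- if (n_cycles > 0)
      pmax(0.1, stats::rnorm(n_cycles, cfg$stride_length_mean, cfg$stride_length_sd))
    else numeric(0)

    labels <- ifelse(fog_mask, "fog", "no_fog")
    rec <- imu_recording(time, accel, gyro, fs, labels,
                         subject_id = paste0("synth", cfg$seed))
    truth <- structure(
      list(fog_mask = fog_mask,
           step_times = list(left = steps$times[steps$sides == "left"],
                             right = steps$times[steps$sides == "right"]),
           stride_lengths = strides,
           episodes = episodes),
      class = "gait_truth")
    list(recording = rec, truth = truth)
  })
}

# Half-sine angular-velocity pulse (width 0.2 s) centred on each foot strike;
# lateral axes carry scaled-down copies.
gyro_step_pulses <- function(time, step_times, fs, peak) {
  n <- length(time)
  g <- rep(0, n)
  if (peak > 0 && length(step_times)) {
    w <- 0.2
    for (ts in step_times) {
      i0 <- max(1L, ceiling((ts - w / 2) * fs) + 1L)
      i1 <- min(n, floor((ts + w / 2) * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      g[idx] <- g[idx] + peak * cos(pi * (time[idx] - ts) / w)^2
    }
  }
  cbind(gx = g, gy = 0.3 * g, gz = 0.15 * g)
}

#' Generate a synthetic gait trajectory with known stride lengths
#'
#' Constructs a forward shank displacement profile from piecewise
#' quintic-smoothstep gait cycles and differentiates it analytically, so that
#' double integration of the (noise- and bias-free) horizontal acceleration
#' recovers the per-cycle stride lengths exactly up to quadrature error. The
#' smoothstep has zero velocity and acceleration at every cycle boundary,
#' which makes the zero-velocity-update assumption of the stride-length
#' estimator exactly true.
#'
#' A constant accelerometer bias can be injected to exercise drift
#' correction; it alters the sensed acceleration but not the kinematic truth.
#'
#' @param config a [synthetic_config()]; `stride_length_mean` must be > 0.
#' @param accel_bias constant additive accelerometer bias on the forward
#'   axis, m/s^2.
#' @param n_cycles optional override of the number of gait cycles; default is
#'   as many as fit in `config$duration` (one cycle lasts
#'   `2 * 60 / step_frequency` seconds).
#' @return As [generate_recording()]: list with `recording` and `truth`;
#'   `truth$stride_lengths` holds the exact per-cycle displacements.
#' @export
generate_trajectory <- function(config, accel_bias = 0, n_cycles = NULL) {
  validate_synthetic_config(config)
  cfg <- config
  if (cfg$stride_length_mean <= 0) {
    stop("invalid synthetic_config: stride_length_mean must be > 0", call. = FALSE)
  }
  fs <- cfg$sampling_rate
  cycle_T <- 2 * 60 / cfg$step_frequency
  if (is.null(n_cycles)) n_cycles <- floor(cfg$duration / cycle_T)
  if (n_cycles < 1) stop("no gait cycles fit in the configured duration", call. = FALSE)

  with_seed(cfg$seed, {
    strides <- pmax(0.1, stats::rnorm(n_cycles, cfg$stride_length_mean,
                                      cfg$stride_length_sd))
    total_T <- n_cycles * cycle_T
    n <- round(total_T * fs) + 1L
    time <- (seq_len(n) - 1L) / fs

    cyc <- pmin(floor(time / cycle_T), n_cycles - 1)
    u <- time / cycle_T - cyc
    # quintic smoothstep s(u) = 10u^3 - 15u^4 + 6u^5: s'' = (60u-180u^2+120u^3)
    L <- strides[cyc + 1]
    acc_true <- L / cycle_T^2 * (60 * u - 180 * u^2 + 120 * u^3)
    acc_sensed <- acc_true + accel_bias
    if (cfg$noise_sd > 0) acc_sensed <- acc_sensed + stats::rnorm(n, 0, cfg$noise_sd)

    accel <- cbind(ax = acc_sensed,
                   ay = if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else rep(0, n),
                   az = if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else rep(0, n))

    left <- (0:n_cycles) * cycle_T
    right <- left[-length(left)] + cycle_T / 2
    step_times <- sort(c(left, right))
    gyro <- gyro_step_pulses(time, step_times, fs, cfg$gyro_peak_amplitude)

    rec <- imu_recording(time, accel, gyro, fs,
                         labels = rep("no_fog", n),
                         subject_id = paste0("traj", cfg$seed))
    truth <- structure(
      list(fog_mask = rep(FALSE, n),
           step_times = list(left = left, right = right),
           stride_lengths = strides,
           episodes = data.frame(start = numeric(0), end = numeric(0),
                                 mode = character(0))),
      class = "gait_truth")
    list(recording = rec, truth = truth)
  })
}

#' Emit a gait event log from ground truth
#'
#' Converts generator ground truth into the timestamped event stream an
#' observer would produce by key-stroking foot strikes and FOG start/end
#' against video, optionally with Gaussian keystroke latency jitter.
#'
#' @param config a [synthetic_config()] (supplies the seed for jitter).
#' @param truth a `gait_truth` as returned by the generators.
#' @param jitter_sd observer latency standard deviation, s (default 0).
#' @return A [gait_event_log()].
#' @export
generate_event_log <- function(config, truth, jitter_sd = 0) {
  validate_synthetic_config(config)
  ev <- data.frame(time = numeric(0), type = character(0),
                   stringsAsFactors = FALSE)
  add <- function(times, type) {
    if (length(times))
      rbind(ev, data.frame(time = times, type = type, stringsAsFactors = FALSE))
    else ev
  }
  ev <- add(truth$step_times$left, "strike_left")
  ev <- add(truth$step_times$right, "strike_right")
  ev <- add(truth$episodes$start, "freeze_start")
  ev <- add(truth$episodes$end, "freeze_end")
  if (jitter_sd > 0) {
    ev$time <- with_seed(config$seed, ev$time + stats::rnorm(nrow(ev), 0, jitter_sd))
    ev$time <- pmax(ev$time, 0)
  }
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]
  gait_event_log(ev$time, ev$type, observer_id = "synthetic")
}
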