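test_that("configuration invariants are enforced with named errors", {
  expect_error(synthetic_config(sampling_rate = 12), "sampling_rate")
  expect_error(synthetic_config(freeze_tremble_frequency = 10), "freeze_tremble_frequency")
  expect_error(synthetic_config(step_frequency = 20), "step_frequency")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(fog_mode_mix = 1.5), "fog_mode_mix")
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- synthetic_config(duration = 30, seed = 7)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$accel, b$recording$accel)
  expect_identical(a$recording$gyro, b$recording$gyro)
  expect_identical(a$truth$step_times, b$truth$step_times)
  # and the generator does not disturb the session RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_recording(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a freeze-free minute of walking carries one gyro peak per step", {
  cfg <- synthetic_config(duration = 60, step_frequency = 100,
                          fog_episode_rate = 0, seed = 2)
  sim <- generate_recording(cfg)
  expect_false(any(sim$truth$fog_mask))
  n_truth <- length(sim$truth$step_times$left) + length(sim$truth$step_times$right)
  expect_lte(abs(n_truth - 100), 1)
  # independent brute-force peak scan of the gyro trace
  g <- sim$recording$gyro[, "gx"]
  thr <- 0.5 * max(g)
  above <- g > thr
  runs <- rle(above)
  expect_lte(abs(sum(runs$values) - 100), 1)
})

test_that("zero amplitudes yield an all-zero signal and no steps", {
  cfg <- synthetic_config(duration = 20, walk_band_amplitude = 0,
                          freeze_tremble_amplitude = 0, noise_sd = 0,
                          gyro_peak_amplitude = 0, seed = 1)
  sim <- generate_recording(cfg)
  expect_true(all(sim$recording$accel == 0))
  expect_true(all(sim$recording$gyro == 0))
  expect_length(sim$truth$step_times$left, 0)
  expect_length(sim$truth$step_times$right, 0)
})

test_that("walking and trembling segments are spectrally separated", {
  cfg <- synthetic_config(duration = 240, noise_sd = 0, seed = 4,
                          fog_mode_mix = 1)  # all trembling
  sim <- generate_recording(cfg)
  fs <- cfg$sampling_rate
  pick_window <- function(mask_value) {
    # first 256-sample run entirely inside (or outside) episodes
    r <- rle(sim$truth$fog_mask)
    ends <- cumsum(r$lengths)
    i <- which(r$values == mask_value & r$lengths >= 300)[1]
    expect_false(is.na(i))  # this seed has long walking and trembling runs
    start <- ends[i] - r$lengths[i] + 21
    seq(start, start + 255)
  }
  for (axis in 1:3) {
    walkw <- sim$recording$accel[pick_window(FALSE), axis]
    fogw <- sim$recording$accel[pick_window(TRUE), axis]
    walk_frac <- oracle_band_power(walkw, fs, c(0.5, 3)) /
      oracle_band_power(walkw, fs, c(0.5, 8), upper_inclusive = TRUE)
    fog_frac <- oracle_band_power(fogw, fs, c(3, 8), upper_inclusive = TRUE) /
      oracle_band_power(fogw, fs, c(0.5, 8), upper_inclusive = TRUE)
    expect_gte(walk_frac, 0.9)
    expect_gte(fog_frac, 0.9)
  }
})

test_that("fog mask matches the episode list exactly", {
  cfg <- synthetic_config(duration = 180, seed = 9)
  sim <- generate_recording(cfg)
  t <- sim$recording$time
  mask <- rep(FALSE, length(t))
  ep <- sim$truth$episodes
  for (i in seq_len(nrow(ep))) mask[t >= ep$start[i] & t < ep$end[i]] <- TRUE
  expect_identical(sim$truth$fog_mask, mask)
  expect_identical(sim$recording$labels, ifelse(mask, "fog", "no_fog"))
  # no step inside any episode
  steps <- sort(unlist(sim$truth$step_times))
  for (i in seq_len(nrow(ep))) {
    expect_false(any(steps > ep$start[i] & steps < ep$end[i]))
  }
})

test_that("episode durations recover their configured mean over many draws", {
  durs <- unlist(lapply(1:20, function(s) {
    ep <- generate_recording(synthetic_config(duration = 300, seed = 100 + s,
                                              fog_duration_sd = 2))$truth$episodes
    # drop episodes clipped by the recording end
    ep$end[ep$end < 300] - ep$start[ep$end < 300]
  }))
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 8), 3 * se + 0.5)
})

test_that("trajectory strides are exact by construction and bias-invariant", {
  cfg <- synthetic_config(duration = 70, stride_length_sd = 0, noise_sd = 0,
                          seed = 3)
  tr <- generate_trajectory(cfg)
  expect_true(all(tr$truth$stride_lengths == 1.2))
  tr_bias <- generate_trajectory(cfg, accel_bias = 0.05)
  expect_identical(tr_bias$truth$stride_lengths, tr$truth$stride_lengths)
  expect_false(identical(tr_bias$recording$accel[, "ax"],
                         tr$recording$accel[, "ax"]))
  # reproducible under a fixed seed with stride variability
  cfg2 <- synthetic_config(duration = 70, stride_length_sd = 0.1, seed = 5)
  expect_identical(generate_trajectory(cfg2)$truth$stride_lengths,
                   generate_trajectory(cfg2)$truth$stride_lengths)
  expect_error(generate_trajectory(synthetic_config(duration = 0.5)), "no gait cycles")
})

test_that("event logs mirror ground truth, with optional reproducible jitter", {
  cfg <- synthetic_config(duration = 120, seed = 6)
  sim <- generate_recording(cfg)
  log <- generate_event_log(cfg, sim$truth)
  expect_setequal(log$time[log$type == "strike_left"], sim$truth$step_times$left)
  expect_equal(sum(log$type == "freeze_start"), nrow(sim$truth$episodes))
  expect_equal(sum(log$type == "freeze_end"), nrow(sim$truth$episodes))
  # freeze starts/ends strictly alternate (validated by the constructor)
  fz <- log$type[log$type %in% c("freeze_start", "freeze_end")]
  expect_identical(fz, rep(c("freeze_start", "freeze_end"), length(fz) / 2))
  j1 <- generate_event_log(cfg, sim$truth, jitter_sd = 0.05)
  j2 <- generate_event_log(cfg, sim$truth, jitter_sd = 0.05)
  expect_identical(j1$time, j2$time)
  expect_false(identical(j1$time, log$time))
})
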