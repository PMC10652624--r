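test_that("steps are recovered exactly on noiseless gait", {
  cfg <- synthetic_config(duration = 24, step_frequency = 100,
                          fog_episode_rate = 0, noise_sd = 0, seed = 1)
  sim <- generate_recording(cfg)
  truth <- sort(unlist(sim$truth$step_times))
  expect_length(truth, 40)
  det <- detect_steps(sim$recording)
  expect_length(det, 40)
  expect_lt(max(abs(det - truth)), 0.05)
  flat <- imu_recording((0:999) / 100, matrix(0, 1000, 3),
                        gyro = matrix(0, 1000, 3), sampling_rate = 100)
  expect_length(detect_steps(flat), 0)
  expect_error(detect_steps(imu_recording((0:999) / 100, matrix(0, 1000, 3),
                                          sampling_rate = 100)),
               "no gyroscope")
})

test_that("step counts degrade gracefully with default sensor noise", {
  errs <- vapply(1:10, function(s) {
    cfg <- synthetic_config(duration = 60, fog_episode_rate = 0, seed = 200 + s)
    sim <- generate_recording(cfg)
    n_truth <- length(unlist(sim$truth$step_times))
    abs(length(detect_steps(sim$recording)) - n_truth) / n_truth
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("step frequency is count over duration", {
  expect_equal(step_frequency(seq(0.3, by = 0.6, length.out = 20), 12), 100)
  expect_equal(step_frequency(numeric(0), 30), 0)
  expect_error(step_frequency(1:3, 0), "duration")
  # event-log path counts both sides
  log <- gait_event_log(seq(0.3, by = 0.6, length.out = 20),
                        rep(c("strike_left", "strike_right"), 10))
  expect_equal(step_frequency(log, 12), 100)
  # IMU path agrees with the log path on a clean trial
  cfg <- synthetic_config(duration = 30, fog_episode_rate = 0, noise_sd = 0,
                          seed = 3)
  sim <- generate_recording(cfg)
  log2 <- generate_event_log(cfg, sim$truth)
  expect_lt(abs(step_frequency(detect_steps(sim$recording), 30) -
                step_frequency(log2, 30)), 1)
})

test_that("symmetry index matches its worked cases", {
  # perfect alternation every 0.55 s -> exactly zero
  t <- seq(0, by = 0.55, length.out = 12)
  log <- gait_event_log(t, rep(c("strike_left", "strike_right"), 6))
  expect_equal(symmetry_index(log), 0)
  # L->R 0.5 s, R->L 0.6 s -> |0.5-0.6|/0.55
  tt <- cumsum(c(0, rep(c(0.5, 0.6), 5)))
  log2 <- gait_event_log(tt, rep(c("strike_left", "strike_right"), length.out = 11))
  expect_equal(symmetry_index(log2), 0.1 / 0.55, tolerance = 1e-12)
  one_sided <- gait_event_log(c(1, 2, 3), rep("strike_left", 3))
  expect_warning(si <- symmetry_index(one_sided), "undefined")
  expect_true(is.na(si))
})

test_that("stride integration is exact without bias and bias-robust with ZUPT", {
  cfg <- synthetic_config(duration = 70, noise_sd = 0, stride_length_sd = 0.1,
                          seed = 4)
  tr <- generate_trajectory(cfg)
  est <- stride_lengths(tr$recording, tr$truth$step_times)
  expect_equal(length(est), length(tr$truth$stride_lengths))
  expect_lt(max(abs(est - tr$truth$stride_lengths) / tr$truth$stride_lengths), 0.01)
  # constant bias: linear velocity detrend removes it exactly
  trb <- generate_trajectory(cfg, accel_bias = 0.05)
  estb <- stride_lengths(trb$recording, trb$truth$step_times)
  expect_lt(max(abs(estb - trb$truth$stride_lengths) / trb$truth$stride_lengths), 0.01)
  # alternating plain-vector input: odd entries are cycle boundaries
  inter <- sort(unlist(tr$truth$step_times))
  est2 <- stride_lengths(tr$recording, inter, alternating = TRUE)
  expect_equal(est2, est)
  # zero acceleration -> zero strides
  flat <- imu_recording((0:2999) / 100, matrix(0, 3000, 3), sampling_rate = 100)
  expect_true(all(stride_lengths(flat, c(0, 1.2, 2.4, 3.6)) == 0))
  expect_warning(out <- stride_lengths(flat, c(1)), "fewer than one")
  expect_length(out, 0)
})

test_that("freeze metrics come out in counts, seconds and percent", {
  fm <- freeze_metrics(toy_event_log(), c(0, 60))
  expect_equal(fm$freeze_count, 3)
  expect_equal(fm$cumulative_freeze_time, 10)
  expect_equal(fm$freeze_time_fraction, 100 * 10 / 60, tolerance = 1e-12)
  empty <- gait_event_log(numeric(0), character(0))
  fm0 <- freeze_metrics(empty, c(0, 60))
  expect_equal(unlist(fm0[1:3]), c(freeze_count = 0, cumulative_freeze_time = 0,
                                   freeze_time_fraction = 0))
  # clipping an interval that spills over the window warns
  log <- gait_event_log(c(50, 70), c("freeze_start", "freeze_end"))
  expect_warning(fmc <- freeze_metrics(log, c(0, 60)), "clipped")
  expect_equal(fmc$cumulative_freeze_time, 10)
})

test_that("prediction tracks merge into episodes with gap tolerance", {
  track <- structure(
    data.frame(window_end_time = seq(1, by = 0.32, length.out = 10),
               probability = 0,
               label_pred = c("no_fog", "fog", "fog", "no_fog", "fog",
                              "fog", "no_fog", "no_fog", "no_fog", "fog")),
    class = c("fog_track", "data.frame"))
  fm1 <- freeze_metrics(track, c(0, 10), gap_tolerance = 1)
  expect_equal(fm1$freeze_count, 2)  # windows 2-6 merge across the 1-gap; 10 alone
  fm0 <- freeze_metrics(track, c(0, 10), gap_tolerance = 0)
  expect_equal(fm0$freeze_count, 3)
})

test_that("observer %CV matches its definition", {
  expect_equal(observer_cv(c(10, 10, 10)), 0)
  expect_equal(observer_cv(c(9, 10, 11)), 10)
  expect_equal(observer_cv(rbind(c(9, 10, 11), c(18, 20, 22))), 10)
  expect_error(observer_cv(matrix(1:3, ncol = 1)), ">= 2 observers")
  expect_warning(cv <- observer_cv(c(-1, 0, 1)), "zero mean")
  expect_true(is.na(cv))
})

test_that("gait summary identities hold on a synthetic trial", {
  cfg <- synthetic_config(duration = 120, seed = 8)
  sim <- generate_recording(cfg)
  log <- generate_event_log(cfg, sim$truth)
  gs <- gait_summary(log, completion_window = c(0, 120), recording = sim$recording)
  expect_equal(gs$step_frequency, gs$step_count / gs$completion_time * 60)
  expect_equal(gs$freeze_time_fraction,
               100 * gs$cumulative_freeze_time / gs$completion_time)
  expect_equal(gs$freeze_count, nrow(sim$truth$episodes))
  expect_equal(gs$step_count, length(unlist(sim$truth$step_times)))
})
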