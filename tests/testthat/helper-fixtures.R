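# Shared fixtures, built in code. Expensive ones are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A pure sinusoid analysis window.
tone_window <- function(freq, fs = 100, n = 256, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Independent periodogram oracle: direct |FFT|^2 normalization, written from
# the definition, not via package helpers.
oracle_band_power <- function(w, fs, band, upper_inclusive = FALSE) {
  n <- length(w)
  X <- fft(w)
  half <- n %/% 2
  p <- Mod(X[1:(half + 1)])^2 / n^2
  if (half >= 2) p[2:half] <- 2 * p[2:half]
  f <- (0:half) * fs / n
  sel <- if (upper_inclusive) f >= band[1] & f <= band[2] else f >= band[1] & f < band[2]
  sum(p[sel])
}

# Short labeled cohort for classifier tests (3 subjects, 2 min each).
small_cohort_features <- function() {
  cached("small_cohort", {
    do.call(rbind, lapply(1:3, function(s) {
      sim <- generate_recording(synthetic_config(duration = 120, seed = s))
      extract_features(sim$recording, hop = 32)
    }))
  })
}

small_model <- function() {
  cached("small_model", fog_train(small_cohort_features(), forest_config()))
}

# An event log with known metric values.
toy_event_log <- function() {
  times <- c(10, 12, 20, 23, 40, 45)
  types <- rep(c("freeze_start", "freeze_end"), 3)
  gait_event_log(times, types)
}
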