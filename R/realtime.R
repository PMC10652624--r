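#' Cue controller configuration
#'
#' Reproduces the study's two cueing modes in simulation. Responsive cueing
#' delivers rhythmic vibration only when FOG is detected and stops a few
#' seconds after walking resumes; continuous cueing runs for the whole
#' stream. The automated trigger debounce (`min_consecutive_fog_windows`)
#' guards against isolated false-positive windows; the human operator played
#' this role in the original protocol, so the debounce rule is this
#' package's own addition.
#'
#' @param mode `"none"`, `"responsive"`, or `"continuous"`.
#' @param cue_frequency vibration burst rhythm, Hz; set near the wearer's
#'   natural step rate.
#' @param cue_intensity arbitrary units.
#' @param stop_delay seconds of continued cueing after the first non-FOG
#'   prediction run (default 3 s).
#' @param min_consecutive_fog_windows FOG windows required to trigger
#'   (default 3).
#' @param legs which legs are cued (the study cued both).
#' @return A list of class `cue_config`.
#' @export
cue_config <- function(mode = c("responsive", "continuous", "none"),
                       cue_frequency = 1.7, cue_intensity = 1,
                       stop_delay = 3, min_consecutive_fog_windows = 3L,
                       legs = "both") {
  mode <- match.arg(mode)
  stopifnot(stop_delay >= 0, min_consecutive_fog_windows >= 1)
  structure(list(mode = mode, cue_frequency = cue_frequency,
                 cue_intensity = cue_intensity, stop_delay = stop_delay,
                 min_consecutive_fog_windows = as.integer(min_consecutive_fog_windows),
                 legs = legs),
            class = "cue_config")
}

#' Run the streaming detection and cueing pipeline over a recording
#'
#' Processes samples strictly one at a time, with no lookahead: each sample
#' updates the per-axis sliding DFTs, and once the window is warm a
#' prediction is emitted every `hop` samples (hop 1 emits per sample, as the
#' embedded device would). The cue controller consumes the prediction stream
#' causally. Tree voting is applied to the causally-computed feature
#' vectors in one vectorized pass afterwards — each window's probability
#' depends only on its own features, so this is identical to voting inside
#' the loop.
#'
#' @param recording an [imu_recording()].
#' @param model a [fog_train()] forest.
#' @param bands a [band_definition()].
#' @param cue a [cue_config()].
#' @param hop prediction stride in samples (default 1).
#' @return A list of class `stream_result`: `track` (a `fog_track`),
#'   `cue_trace` (intervals + trigger events), and `budget` — arithmetic
#'   operations per sample for the streaming spectral path, its tracked bin
#'   count, and the amortized renormalization cost, demonstrating per-sample
#'   cost independent of the window length.
#' @export
stream <- function(recording, model, bands = band_definition(),
                   cue = cue_config("none"), hop = 1L) {
  feats <- extract_features(recording, bands, hop = hop, mode = "streaming")
  if (!nrow(feats)) {
    stop("recording shorter than one analysis window; nothing to stream",
         call. = FALSE)
  }
  track <- fog_predict(model, feats)

  n <- length(recording$time)
  nb <- length(sdft_init(recording$sampling_rate, bands)$k)
  budget <- list(
    tracked_bins = nb,
    ops_per_sample_stream = 3 * 10 * nb,        # three axes, constant per sample
    ops_per_sample_renorm_amortized = 3 * 8 * bands$window_length * nb / 4096,
    window_length = bands$window_length,
    n_samples = n)

  trace <- run_cue_controller(track, cue, end_time = recording$time[n])
  structure(list(track = track, cue_trace = trace, budget = budget),
            class = "stream_result")
}

# Causal cue state machine over a prediction track.
run_cue_controller <- function(track, cue, end_time) {
  empty <- list(intervals = data.frame(start = numeric(0), end = numeric(0),
                                       leg = character(0)),
                trigger_events = data.frame(time = numeric(0),
                                            cause = character(0)))
  if (cue$mode == "none" || !nrow(track)) return(empty)
  t <- track$window_end_time
  if (cue$mode == "continuous") {
    return(list(intervals = data.frame(start = t[1], end = end_time,
                                       leg = cue$legs),
                trigger_events = data.frame(time = t[1],
                                            cause = "continuous_start")))
  }
  fog <- track$label_pred == "fog"
  consec <- 0L
  on <- FALSE
  off_at <- NA_real_
  starts <- ends <- numeric(0)
  trig <- numeric(0)
  for (i in seq_along(t)) {
    if (on && !is.na(off_at)) {
      if (fog[i]) {
        off_at <- NA_real_                      # walking did not resume
      } else if (t[i] >= off_at) {
        ends <- c(ends, off_at); on <- FALSE; off_at <- NA_real_; consec <- 0L
      }
    }
    if (fog[i]) {
      consec <- consec + 1L
      if (!on && consec >= cue$min_consecutive_fog_windows) {
        on <- TRUE; starts <- c(starts, t[i]); trig <- c(trig, t[i])
        off_at <- NA_real_
      }
    } else {
      consec <- 0L
      if (on && is.na(off_at)) off_at <- t[i] + cue$stop_delay
    }
  }
  if (on) ends <- c(ends, if (!is.na(off_at)) min(off_at, end_time) else end_time)
  list(intervals = data.frame(start = starts, end = ends,
                              leg = rep(cue$legs, length(starts))),
       trigger_events = data.frame(time = trig,
                                   cause = rep("fog_onset", length(trig))))
}

#' Verify streaming/batch equivalence on a recording
#'
#' Guards the sliding-DFT streaming claim: window-for-window, the streaming
#' pipeline must produce the same features and probabilities as the batch
#' FFT path. A fault-injection hook (`corrupt_at`) perturbs the streaming
#' DFT state mid-stream so the check's power can itself be tested.
#'
#' @param recording an [imu_recording()] long enough for >= 10 windows.
#' @param model a [fog_train()] forest.
#' @param bands a [band_definition()].
#' @param hop window hop, samples.
#' @param tolerance maximum tolerated absolute probability difference.
#' @param feature_tolerance maximum tolerated relative feature difference;
#'   checked as well as the probabilities, since a state fault need not flip
#'   any tree vote.
#' @param corrupt_at optional sample index at which the x-axis streaming
#'   state is corrupted (testing hook).
#' @return List: `equivalent`, `n_windows`, `max_abs_diff_probability`,
#'   `max_rel_diff_features`, `first_divergent_window` (`NA` when
#'   equivalent).
#' @export
replay_equivalence <- function(recording, model, bands = band_definition(),
                               hop = 32L, tolerance = 1e-9,
                               feature_tolerance = 1e-6,
                               corrupt_at = NULL) {
  N <- bands$window_length
  if (length(recording$time) < N + 9 * hop) {
    stop("recording too short for a meaningful replay check (>= 10 windows)",
         call. = FALSE)
  }
  batch <- extract_features(recording, bands, hop = hop, mode = "batch")
  streamed <- if (is.null(corrupt_at)) {
    extract_features(recording, bands, hop = hop, mode = "streaming")
  } else {
    corrupt_streaming_features(recording, bands, hop, corrupt_at)
  }
  fcols <- feature_columns(batch)
  fb <- as.matrix(batch[fcols]); fsm <- as.matrix(streamed[fcols])
  rel <- abs(fsm - fb) / pmax(abs(fb), 1e-12)
  pb <- fog_predict(model, batch)$probability
  ps <- fog_predict(model, streamed)$probability
  dp <- abs(ps - pb)
  div <- which(dp > tolerance | apply(rel, 1, max) > feature_tolerance)
  list(equivalent = !length(div),
       n_windows = nrow(batch),
       max_abs_diff_probability = max(dp),
       max_rel_diff_features = max(rel),
       first_divergent_window = if (length(div)) div[1] else NA_integer_)
}

corrupt_streaming_features <- function(recording, bands, hop, corrupt_at) {
  N <- bands$window_length
  n <- length(recording$time)
  ends <- seq.int(N, n, by = hop)
  fs <- recording$sampling_rate
  axes <- c("x", "y", "z")
  out <- data.frame(window_end_time = recording$time[ends])
  for (a in 1:3) {
    st <- sdft_init(fs, bands)
    m <- matrix(NA_real_, length(ends), 6, dimnames = list(NULL, feature_names()))
    j <- 1L
    x <- recording$accel[, a]
    for (i in seq_len(n)) {
      sdft_update(st, x[i])
      if (a == 1L && i == corrupt_at) st$coef <- st$coef + 1
      if (j <= length(ends) && i == ends[j]) {
        m[j, ] <- sdft_features(st); j <- j + 1L
      }
    }
    colnames(m) <- paste0(feature_names(), "_", axes[a])
    out <- cbind(out, as.data.frame(m))
  }
  out$label <- window_labels(recording$labels, ends, N)
  out$subject_id <- recording$subject_id
  class(out) <- c("window_features", "data.frame")
  out
}
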