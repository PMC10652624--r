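#' Extract per-window FOG features from a recording
#'
#' For every analysis window (default 256 samples) and every accelerometer
#' axis, computes the six features used by the FOG classifier: freeze index,
#' total band power (0.5-8 Hz), variance, L1 norm, L2 norm, and spectral
#' entropy. Windows are placed at `window_length, window_length + hop, ...`
#' samples (their end positions); `window_end_time` is the time of the last
#' sample in the window, so every feature vector is causal.
#'
#' The window label is the majority of the per-sample labels, with ties
#' resolved to `fog` (conservative for a detector whose miss cost is high).
#'
#' Both computation modes produce the same values: `"batch"` runs an FFT per
#' window, `"streaming"` pushes samples one at a time through the sliding
#' DFT ([sdft_init()]) exactly as the embedded pipeline would.
#'
#' @param recording an [imu_recording()].
#' @param bands a [band_definition()].
#' @param hop window hop in samples. The streaming detector uses hop 1; the
#'   default 32 decorrelates training windows.
#' @param mode `"batch"` or `"streaming"`.
#' @return A data frame of class `window_features`: `window_end_time`,
#'   columns `<feature>_<axis>` for axes x/y/z, `label`, `subject_id`, plus
#'   attributes `sampling_rate` and `bands`. Zero rows (with a warning) if
#'   the recording is shorter than one window.
#' @export
extract_features <- function(recording, bands = band_definition(), hop = 32L,
                             mode = c("batch", "streaming")) {
  mode <- match.arg(mode)
  stopifnot(hop >= 1)
  N <- bands$window_length
  n <- length(recording$time)
  if (n < N) {
    warning("recording shorter than one analysis window; no features extracted")
    return(empty_features())
  }
  ends <- seq.int(N, n, by = hop)
  fs <- recording$sampling_rate

  feat_axis <- if (mode == "batch") {
    lapply(1:3, function(a) batch_axis_features(recording$accel[, a], ends, fs, bands))
  } else {
    lapply(1:3, function(a) streaming_axis_features(recording$accel[, a], ends, fs, bands))
  }

  out <- data.frame(window_end_time = recording$time[ends])
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    m <- feat_axis[[a]]
    colnames(m) <- paste0(colnames(m), "_", axes[a])
    out <- cbind(out, as.data.frame(m))
  }
  out$label <- window_labels(recording$labels, ends, N)
  out$subject_id <- recording$subject_id
  attr(out, "sampling_rate") <- fs
  attr(out, "bands") <- bands
  class(out) <- c("window_features", "data.frame")
  out
}

empty_features <- function() {
  out <- data.frame(window_end_time = numeric(0))
  class(out) <- c("window_features", "data.frame")
  out
}

feature_names <- function() {
  c("freeze_index", "band_power", "variance", "l1_norm", "l2_norm", "entropy")
}

#' @rdname extract_features
#' @export
feature_columns <- function(features) {
  grep("^(freeze_index|band_power|variance|l1_norm|l2_norm|entropy)_",
       names(features), value = TRUE)
}

window_labels <- function(labels, ends, N) {
  if (is.null(labels)) return(rep("unannotated", length(ends)))
  vapply(ends, function(e) {
    w <- labels[(e - N + 1):e]
    nf <- sum(w == "fog"); nn <- sum(w == "no_fog"); nu <- sum(w == "unannotated")
    if (nf >= max(nn, nu)) "fog" else if (nn >= nu) "no_fog" else "unannotated"
  }, character(1))
}

# Vectorized batch path: one mvfft over the matrix of windows per axis.
batch_axis_features <- function(x, ends, fs, bands) {
  N <- bands$window_length
  W <- vapply(ends, function(e) x[(e - N + 1):e], numeric(N))
  X <- stats::mvfft(W)
  freq_all <- (0:(N %/% 2)) * fs / N
  kk <- band_bins(freq_all, bands$total_band, upper_inclusive = TRUE)  # 1-based
  freq <- freq_all[kk]
  P <- Mod(X[kk, , drop = FALSE])^2 / N^2
  dbl <- (kk - 1L) != 0L & (kk - 1L) != N %/% 2L
  P[dbl, ] <- 2 * P[dbl, , drop = FALSE]

  wsel <- freq >= bands$walk_band[1] & freq < bands$walk_band[2]
  fsel <- freq >= bands$freeze_band[1] & freq <= bands$freeze_band[2]
  wp <- colSums(P[wsel, , drop = FALSE])
  fp <- colSums(P[fsel, , drop = FALSE])
  tot <- colSums(P)

  Q <- sweep(P, 2, pmax(tot, .Machine$double.xmin), "/")
  H <- -colSums(ifelse(Q > 0, Q * log(Q), 0))
  H[tot <= 0] <- log(nrow(P))

  mu <- colMeans(W)
  varv <- colSums(sweep(W, 2, mu)^2) / N
  cbind(freeze_index = fp / pmax(wp, bands$epsilon_power),
        band_power = tot,
        variance = varv,
        l1_norm = colSums(abs(W)),
        l2_norm = sqrt(colSums(W^2)),
        entropy = H)
}

streaming_axis_features <- function(x, ends, fs, bands) {
  st <- sdft_init(fs, bands)
  out <- matrix(NA_real_, length(ends), 6,
                dimnames = list(NULL, feature_names()))
  j <- 1L
  ne <- length(ends)
  for (i in seq_along(x)) {
    sdft_update(st, x[i])
    if (j <= ne && i == ends[j]) {
      out[j, ] <- sdft_features(st)
      j <- j + 1L
    }
  }
  out
}
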