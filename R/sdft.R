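#' Sliding DFT state for streaming spectral features
#'
#' A full FFT per sample is the bottleneck for embedded real-time freeze
#' detection; because only one of the N window samples changes per
#' acquisition cycle, the DFT coefficients can instead be updated
#' recursively. This state tracks the coefficients of every bin in the total
#' band (0.5-8 Hz by default) plus a ring buffer of the current window for
#' the time-domain features.
#'
#' Per-sample update for each tracked bin k:
#' `X_k <- (X_k - x_oldest + x_new) * exp(2i*pi*k/N)`,
#' after which the tracked coefficients equal the direct DFT of the current
#' window. Floating-point drift is bounded by periodic renormalization: every
#' `renorm_every` samples the coefficients are recomputed from the buffer by
#' direct DFT.
#'
#' The state is an environment (updated in place). Arithmetic is counted per
#' update so the embedded-budget contract — per-sample cost proportional to
#' the number of tracked bins, independent of N — can be asserted by
#' operation counts rather than wall-clock.
#'
#' @param fs sampling rate, Hz.
#' @param bands a [band_definition()].
#' @param renorm_every recompute the tracked bins by direct DFT every this
#'   many updates (default 4096).
#' @return An environment of class `sdft_state`.
#' @export
sdft_init <- function(fs, bands = band_definition(), renorm_every = 4096L) {
  N <- bands$window_length
  freq_all <- (0:(N %/% 2)) * fs / N
  k <- band_bins(freq_all, bands$total_band, upper_inclusive = TRUE) - 1L  # 0-based
  st <- new.env(parent = emptyenv())
  st$N <- N
  st$fs <- fs
  st$bands <- bands
  st$k <- k
  st$freq <- freq_all[k + 1L]
  st$twiddle <- exp(2i * pi * k / N)
  st$coef <- complex(length(k))
  st$buffer <- numeric(N)
  st$pos <- 1L          # index of the oldest sample in the ring
  st$n_seen <- 0L
  st$renorm_every <- as.integer(renorm_every)
  st$since_renorm <- 0L
  st$ops_stream <- 0    # cumulative arithmetic ops in recursive updates
  st$ops_renorm <- 0    # cumulative ops spent on renormalization
  st$n_updates <- 0L
  class(st) <- "sdft_state"
  st
}

#' Push one sample through the sliding DFT
#'
#' @param state an [sdft_init()] state (modified in place).
#' @param x_new the newly acquired sample.
#' @return The state, invisibly.
#' @export
sdft_update <- function(state, x_new) {
  oldest <- state$buffer[state$pos]
  state$coef <- (state$coef - oldest + x_new) * state$twiddle
  state$buffer[state$pos] <- x_new
  state$pos <- if (state$pos == state$N) 1L else state$pos + 1L
  state$n_seen <- state$n_seen + 1L
  state$n_updates <- state$n_updates + 1L
  nb <- length(state$k)
  # 1 complex mul (6 flops) + 2 real add/sub folded into complex adds (4)
  state$ops_stream <- state$ops_stream + 10 * nb
  state$since_renorm <- state$since_renorm + 1L
  if (state$since_renorm >= state$renorm_every) sdft_renormalize(state)
  invisible(state)
}

#' @rdname sdft_update
#' @export
sdft_ready <- function(state) state$n_seen >= state$N

# Current window in acquisition order (oldest first); valid once ready.
sdft_window <- function(state) {
  if (state$pos == 1L) state$buffer
  else state$buffer[c(state$pos:state$N, 1:(state$pos - 1L))]
}

sdft_renormalize <- function(state) {
  w <- sdft_window(state)
  m <- seq_len(state$N) - 1L
  state$coef <- vapply(state$k, function(k)
    sum(w * exp(-2i * pi * k * m / state$N)), complex(1))
  state$ops_renorm <- state$ops_renorm + 8 * state$N * length(state$k)
  state$since_renorm <- 0L
  invisible(state)
}

#' Tracked DFT coefficients of the current window
#'
#' Equal (to accumulation tolerance) to `fft(window)[k + 1]` for the tracked
#' bins `k`.
#'
#' @param state an `sdft_state`.
#' @return Complex vector, one coefficient per tracked bin.
#' @export
sdft_coefficients <- function(state) state$coef

# One-sided periodogram power restricted to the tracked bins, same
# normalization as periodogram().
sdft_band_powers <- function(state) {
  p <- Mod(state$coef)^2 / state$N^2
  dbl <- state$k != 0L & state$k != state$N %/% 2L
  p[dbl] <- 2 * p[dbl]
  p
}

# Full six-feature vector for the current streaming window of one axis.
sdft_features <- function(state) {
  if (!sdft_ready(state)) {
    stop("sliding DFT not warmed up: fewer than N samples seen", call. = FALSE)
  }
  bands <- state$bands
  p <- sdft_band_powers(state)
  wsel <- state$freq >= bands$walk_band[1] & state$freq < bands$walk_band[2]
  fsel <- state$freq >= bands$freeze_band[1] & state$freq <= bands$freeze_band[2]
  wp <- sum(p[wsel]); fp <- sum(p[fsel]); tot <- sum(p)
  ent <- if (tot <= 0) log(length(p)) else {
    q <- p / tot; q <- q[q > 0]; -sum(q * log(q))
  }
  w <- sdft_window(state)
  td <- time_domain_features(w)
  c(freeze_index = fp / max(wp, bands$epsilon_power),
    band_power = tot,
    variance = unname(td["variance"]),
    l1_norm = unname(td["l1_norm"]),
    l2_norm = unname(td["l2_norm"]),
    entropy = ent)
}
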