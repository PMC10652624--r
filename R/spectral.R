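#' Band definitions for FOG spectral features
#'
#' The freeze index contrasts power in the freeze band (3-8 Hz, trembling)
#' with power in the walking band (0.5-3 Hz, locomotion). Band power over the
#' whole 0.5-8 Hz range disambiguates stillness (low power, possibly high
#' freeze index) from trembling (high power, high freeze index).
#'
#' Bin inclusion at band edges is half-open `[f1, f2)` so the walking and
#' freeze bands partition the total band at 3 Hz with no double counting; the
#' 8 Hz upper edge of the total (and hence freeze) band is inclusive.
#'
#' @param walk_band,freeze_band,total_band frequency intervals, Hz.
#' @param window_length analysis window length in samples; must be a power of
#'   two (default 256, about 2.5 s at 100 Hz).
#' @param epsilon_power floor for the walking-band power in the freeze-index
#'   denominator, (m/s^2)^2. Below typical accelerometer noise floors; it
#'   caps, but does not hide, stillness — the band-power feature carries that
#'   information.
#' @return A list of class `band_definition`.
#' @export
band_definition <- function(walk_band = c(0.5, 3), freeze_band = c(3, 8),
                            total_band = c(0.5, 8), window_length = 256L,
                            epsilon_power = 1e-8) {
  if (walk_band[2] != freeze_band[1] || total_band[1] != walk_band[1] ||
      total_band[2] != freeze_band[2]) {
    stop("walk and freeze bands must partition total_band", call. = FALSE)
  }
  if (bitwAnd(window_length, window_length - 1L) != 0L || window_length < 2L) {
    stop("window_length must be a power of two", call. = FALSE)
  }
  if (epsilon_power <= 0) stop("epsilon_power must be positive", call. = FALSE)
  structure(list(walk_band = walk_band, freeze_band = freeze_band,
                 total_band = total_band,
                 window_length = as.integer(window_length),
                 epsilon_power = epsilon_power),
            class = "band_definition")
}

# One-sided periodogram normalized so that the full-spectrum sum equals the
# window mean square (Parseval). Rectangular window: the SDFT recurrence
# used by the streaming path assumes no taper.
periodogram <- function(window, fs) {
  n <- length(window)
  X <- stats::fft(window)
  periodogram_from_dft(X, n, fs)
}

periodogram_from_dft <- function(X, n, fs) {
  half <- n %/% 2
  p <- Mod(X[1:(half + 1)])^2 / n^2
  if (half >= 2) p[2:half] <- 2 * p[2:half]  # double non-DC, non-Nyquist bins
  list(freq = (0:half) * fs / n, power = p)
}

band_bins <- function(freq, band, upper_inclusive = FALSE) {
  if (upper_inclusive) which(freq >= band[1] & freq <= band[2])
  else which(freq >= band[1] & freq < band[2])
}

#' Spectral power of a window in a frequency band
#'
#' Sums the one-sided rectangular-window periodogram over DFT bins whose
#' centre frequency lies in `[f1, f2)` (set `upper_inclusive = TRUE` for the
#' upper edge of the total band). Normalization satisfies Parseval: the sum
#' over the full spectrum equals the mean squared signal.
#'
#' @param window numeric vector, length must equal `bands$window_length` when
#'   a `band_definition` context applies (any length is accepted here).
#' @param fs sampling rate, Hz; must exceed twice the upper band edge.
#' @param band numeric length-2 interval, Hz.
#' @param upper_inclusive include bins at exactly `band[2]`.
#' @return Band power, (signal units)^2.
#' @export
band_power <- function(window, fs, band, upper_inclusive = FALSE) {
  if (band[2] > fs / 2) {
    stop("band extends beyond the Nyquist frequency", call. = FALSE)
  }
  pg <- periodogram(window, fs)
  sum(pg$power[band_bins(pg$freq, band, upper_inclusive)])
}

#' Freeze index of an analysis window
#'
#' Ratio of freeze-band (3-8 Hz) power to walking-band (0.5-3 Hz) power. The
#' walking-band power is floored at `bands$epsilon_power` so that stillness
#' (both powers near zero) yields a finite, small value instead of a
#' spuriously large ratio; use the band-power feature to tell stillness and
#' trembling apart.
#'
#' @param window numeric vector of `bands$window_length` samples.
#' @param fs sampling rate, Hz.
#' @param bands a [band_definition()].
#' @return Dimensionless ratio >= 0, invariant to rescaling the window (when
#'   above the epsilon guard).
#' @export
freeze_index <- function(window, fs, bands = band_definition()) {
  pg <- periodogram(window, fs)
  fp <- sum(pg$power[band_bins(pg$freq, bands$freeze_band, upper_inclusive = TRUE)])
  wp <- sum(pg$power[band_bins(pg$freq, bands$walk_band)])
  fp / max(wp, bands$epsilon_power)
}

#' Time-domain window features
#'
#' Variance (population, divisor N), L1 norm and L2 norm of the raw (not
#' mean-removed) window.
#'
#' @param window numeric vector.
#' @return Named numeric vector `c(variance, l1_norm, l2_norm)`.
#' @export
time_domain_features <- function(window) {
  if (!length(window)) stop("empty window", call. = FALSE)
  n <- length(window)
  c(variance = sum((window - mean(window))^2) / n,
    l1_norm = sum(abs(window)),
    l2_norm = sqrt(sum(window^2)))
}

#' Spectral entropy of an analysis window
#'
#' Shannon entropy (nats) of the periodogram normalized over the bins of the
#' total band (0.5-8 Hz): `H = -sum p_k log p_k` with
#' `p_k = P_k / sum P_k`. A zero-power window returns the maximum
#' `log(n_bins)` by convention — an all-zero spectrum is uninformative about
#' frequency content.
#'
#' @inheritParams freeze_index
#' @return Entropy in `[0, log(n_bins)]`, nats.
#' @export
spectral_entropy <- function(window, fs, bands = band_definition()) {
  pg <- periodogram(window, fs)
  p <- pg$power[band_bins(pg$freq, bands$total_band, upper_inclusive = TRUE)]
  tot <- sum(p)
  if (tot <= 0) return(log(length(p)))
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

n_total_band_bins <- function(fs, bands) {
  freq <- (0:(bands$window_length %/% 2)) * fs / bands$window_length
  length(band_bins(freq, bands$total_band, upper_inclusive = TRUE))
}
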