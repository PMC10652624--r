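#' IMU recording container
#'
#' Bundles a timestamped 6-DoF sample stream from one leg-worn sensor:
#' tri-axial acceleration (m/s^2), optional tri-axial angular velocity
#' (deg/s), and optional per-sample FOG annotation.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param accel numeric matrix (or data frame) with columns `ax`, `ay`, `az`
#'   in m/s^2, one row per sample.
#' @param gyro optional matrix with columns `gx`, `gy`, `gz` in deg/s.
#' @param sampling_rate nominal sampling rate in Hz. The median observed
#'   sampling interval must agree with `1/sampling_rate` within 10%.
#' @param labels optional per-sample factor/character with levels
#'   `"unannotated"`, `"no_fog"`, `"fog"`.
#' @param subject_id,segment_id identifiers carried through to feature
#'   extraction and cross-validation grouping.
#'
#' @return An object of class `imu_recording`: a list with fields `time`,
#'   `accel`, `gyro`, `labels`, `sampling_rate`, `subject_id`, `segment_id`.
#' @export
imu_recording <- function(time, accel, gyro = NULL, sampling_rate,
                          labels = NULL, subject_id = "S0", segment_id = "seg0") {
  time <- as.numeric(time)
  accel <- as.matrix(accel)
  storage.mode(accel) <- "double"
  colnames(accel) <- c("ax", "ay", "az")
  if (length(time) != nrow(accel)) {
    stop("accel must have one row per time sample", call. = FALSE)
  }
  dt <- diff(time)
  if (length(dt) && any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("time must be strictly increasing; violation at row %d", bad),
         call. = FALSE)
  }
  if (length(dt)) {
    nominal <- 1 / sampling_rate
    if (abs(stats::median(dt) - nominal) > 0.1 * nominal) {
      stop("median sampling interval disagrees with sampling_rate by more than 10%",
           call. = FALSE)
    }
  }
  if (!is.null(gyro)) {
    gyro <- as.matrix(gyro)
    storage.mode(gyro) <- "double"
    colnames(gyro) <- c("gx", "gy", "gz")
    if (nrow(gyro) != length(time)) {
      stop("gyro must have one row per time sample", call. = FALSE)
    }
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(time)) {
      stop("labels must have one entry per time sample", call. = FALSE)
    }
    bad <- setdiff(unique(labels), c("unannotated", "no_fog", "fog"))
    if (length(bad)) {
      stop("unknown label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(time = time, accel = accel, gyro = gyro, labels = labels,
         sampling_rate = sampling_rate,
         subject_id = as.character(subject_id),
         segment_id = as.character(segment_id)),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$time)
  dur <- if (n) x$time[n] - x$time[1] else 0
  cat(sprintf("<imu_recording> subject %s, segment %s\n", x$subject_id, x$segment_id))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), gyro: %s, labels: %s\n",
              n, x$sampling_rate, dur,
              if (is.null(x$gyro)) "absent" else "present",
              if (is.null(x$labels)) "absent" else
                paste(sprintf("%.1f%% fog", 100 * mean(x$labels == "fog")))))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) length(x$time)
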