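#' Read an IMU recording from disk
#'
#' Two dialects are supported. The `native_csv` dialect is the package's own
#' round-trippable format: comment lines `# sampling_rate: <Hz>`,
#' `# subject_id: <id>`, `# segment_id: <id>` followed by a CSV table with
#' columns `time_s, ax, ay, az[, gx, gy, gz][, label]` (accelerations in
#' m/s^2, angular velocities in deg/s, times in seconds).
#'
#' The `daphnet` dialect is the whitespace-separated annotated benchmark
#' layout: integer millisecond timestamps, three acceleration channel groups
#' (ankle, thigh, trunk; milli-g), and a trailing annotation column coded
#' 0 = unannotated, 1 = no freeze, 2 = freeze. Only the lower-leg (ankle)
#' channels are retained; milli-g values are converted to m/s^2 with
#' g = 9.80665. Rows coded 0 are kept but flagged `unannotated` (they are
#' excluded from training and from sensitivity/specificity denominators,
#' while remaining available to streaming detection).
#'
#' @param path file path.
#' @param format `"native_csv"` or `"daphnet"`.
#' @param sampling_rate sampling rate override; for `daphnet` the default is
#'   64 Hz, for `native_csv` the header value is used.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, format = c("native_csv", "daphnet"),
                           sampling_rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "native_csv") read_recording_native(path, sampling_rate)
  else read_recording_daphnet(path, sampling_rate %||% 64)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_header_field <- function(lines, key) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(pat, "", hit[1])
}

read_recording_native <- function(path, sampling_rate) {
  lines <- readLines(path, n = 10L)
  fs <- sampling_rate %||% as.numeric(read_header_field(lines, "sampling_rate"))
  if (is.null(fs) || is.na(fs)) {
    stop("native_csv header lacks '# sampling_rate:' and none was supplied",
         call. = FALSE)
  }
  subj <- read_header_field(lines, "subject_id") %||% "S0"
  seg <- read_header_field(lines, "segment_id") %||% "seg0"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop("native_csv must have columns time_s, ax, ay, az", call. = FALSE)
  }
  for (col in c("time_s", "ax", "ay", "az")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("non-numeric value in column '%s'", col), call. = FALSE)
    }
  }
  gyro <- if (all(c("gx", "gy", "gz") %in% names(df)))
    as.matrix(df[, c("gx", "gy", "gz")]) else NULL
  labels <- if ("label" %in% names(df)) df$label else NULL
  imu_recording(df$time_s, as.matrix(df[, c("ax", "ay", "az")]), gyro, fs,
                labels, subject_id = subj, segment_id = seg)
}

MILLI_G_TO_MS2 <- 9.80665 / 1000

read_recording_daphnet <- function(path, sampling_rate) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("malformed benchmark file: ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(df) < 5) {
    stop("annotated benchmark format needs >= 5 columns (time, ankle x/y/z, ..., label)",
         call. = FALSE)
  }
  time <- df[[1]] / 1000  # ms -> s
  accel <- as.matrix(df[, 2:4]) * MILLI_G_TO_MS2
  ann <- df[[ncol(df)]]
  bad <- which(!ann %in% 0:2)
  if (length(bad)) {
    stop(sprintf("invalid annotation code at line %d", bad[1]), call. = FALSE)
  }
  labels <- c("unannotated", "no_fog", "fog")[ann + 1]
  imu_recording(time, accel, NULL, sampling_rate, labels,
                subject_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an IMU recording in the native CSV dialect
#'
#' @param recording an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %.10g", recording$sampling_rate),
               sprintf("# subject_id: %s", recording$subject_id),
               sprintf("# segment_id: %s", recording$segment_id)), con)
  df <- data.frame(time_s = recording$time, recording$accel)
  if (!is.null(recording$gyro)) df <- cbind(df, recording$gyro)
  if (!is.null(recording$labels)) df$label <- recording$labels
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write window feature tables
#'
#' Feature tables are plain CSV with one row per analysis window:
#' `window_end_time`, the per-axis feature columns, and `label`. Values are
#' written with 15 significant digits so a write/read round trip is lossless
#' to better than 1e-12 relative.
#'
#' @param features a `window_features` data frame from [extract_features()].
#' @param path file path.
#' @return `read_features` returns the feature data frame; `write_features`
#'   returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  if (!nrow(features)) stop("no features to write", call. = FALSE)
  num <- vapply(features, is.numeric, logical(1))
  out <- features
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"window_end_time" %in% names(df)) {
    stop("not a feature table: missing window_end_time", call. = FALSE)
  }
  class(df) <- c("window_features", "data.frame")
  df
}

#' Read / write gait event logs
#'
#' Event logs are CSV with columns `time_s`, `event_type`, `side`; validation
#' (event-type vocabulary, alternating freeze pairs) is applied on read via
#' [gait_event_log()].
#'
#' @param log a [gait_event_log()].
#' @param path file path.
#' @return `read_event_log` returns a validated [gait_event_log()].
#' @export
write_event_log <- function(log, path) {
  df <- data.frame(time_s = log$time, event_type = log$type,
                   side = ifelse(is.na(log$side), "", log$side))
  df$time_s <- format(df$time_s, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path, observer_id = "obs1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "event_type") %in% names(df))) {
    stop("event log must have columns time_s, event_type", call. = FALSE)
  }
  gait_event_log(df$time_s, df$event_type, observer_id = observer_id)
}
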