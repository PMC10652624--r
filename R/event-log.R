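#' Gait event log
#'
#' Ordered, timestamped gait events as produced by observer video annotation
#' (key-stroked foot strikes and FOG start/end marks) or by detection.
#'
#' Validation enforces the structural invariants the downstream metrics rely
#' on: non-decreasing times, strictly alternating `freeze_start` /
#' `freeze_end` pairs, and `segment_start` preceding `segment_end`.
#'
#' @param time event times, s.
#' @param type event types; one of `strike_left`, `strike_right`,
#'   `freeze_start`, `freeze_end`, `segment_start`, `segment_end`.
#' @param observer_id identifier of the annotating observer.
#' @return A data frame of class `gait_event_log` with columns `time`,
#'   `type`, `side` (derived from strike events, `NA` otherwise) and an
#'   `observer_id` attribute.
#' @export
gait_event_log <- function(time, type, observer_id = "obs1") {
  allowed <- c("strike_left", "strike_right", "freeze_start", "freeze_end",
               "segment_start", "segment_end")
  type <- as.character(type)
  bad <- setdiff(unique(type), allowed)
  if (length(bad)) {
    stop("unknown event type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  time <- as.numeric(time)
  if (length(time) != length(type)) stop("time and type lengths differ", call. = FALSE)
  o <- order(time)
  time <- time[o]; type <- type[o]
  if (length(time) > 1 && any(diff(time) < 0)) {
    stop("event times must be non-decreasing", call. = FALSE)
  }
  depth <- 0L
  for (i in seq_along(type)) {
    if (type[i] == "freeze_start") {
      depth <- depth + 1L
      if (depth > 1L) stop(sprintf(
        "freeze_start at t=%.3f while a freeze is already open", time[i]), call. = FALSE)
    } else if (type[i] == "freeze_end") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf(
        "freeze_end at t=%.3f without matching freeze_start", time[i]), call. = FALSE)
    }
  }
  if (depth != 0L) stop("unterminated freeze_start", call. = FALSE)
  seg_open <- which(type == "segment_start")
  seg_close <- which(type == "segment_end")
  if (length(seg_close) && (!length(seg_open) || seg_open[1] > seg_close[1])) {
    stop("segment_end precedes segment_start", call. = FALSE)
  }
  side <- rep(NA_character_, length(type))
  side[type == "strike_left"] <- "left"
  side[type == "strike_right"] <- "right"
  structure(data.frame(time = time, type = type, side = side,
                       stringsAsFactors = FALSE),
            observer_id = as.character(observer_id),
            class = c("gait_event_log", "data.frame"))
}

#' Extract freeze intervals from an event log
#'
#' @param log a [gait_event_log()].
#' @return Data frame with columns `start`, `end`, one row per freeze.
#' @export
freeze_intervals <- function(log) {
  s <- log$time[log$type == "freeze_start"]
  e <- log$time[log$type == "freeze_end"]
  data.frame(start = s, end = e)
}

strike_times <- function(log, side = NULL) {
  keep <- log$type %in% c("strike_left", "strike_right")
  if (!is.null(side)) keep <- keep & log$side %in% side
  log$time[keep]
}
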