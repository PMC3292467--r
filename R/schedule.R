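#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records the start time and duration (both in seconds) of
#' every reconstructed frame. Frames must be non-overlapping, strictly
#' ordered and of positive duration; gaps are allowed.
#'
#' @param frame_start_s numeric vector of frame start times (seconds).
#' @param frame_duration_s numeric vector of frame durations (seconds).
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `frame_start_s` and `frame_duration_s`.
#' @examples
#' frame_schedule(c(0, 30), c(30, 30))
#' @export
frame_schedule <- function(frame_start_s, frame_duration_s) {
  if (length(frame_start_s) != length(frame_duration_s))
    stop_petkin("frame starts and durations must have equal length",
                "petkin_invalid_schedule")
  if (length(frame_start_s) == 0L)
    stop_petkin("a schedule needs at least one frame", "petkin_invalid_schedule")
  if (any(!is.finite(frame_start_s)) || any(!is.finite(frame_duration_s)))
    stop_petkin("schedule times must be finite", "petkin_invalid_schedule")
  if (any(frame_duration_s <= 0))
    stop_petkin("all frame durations must be > 0", "petkin_invalid_schedule")
  if (is.unsorted(frame_start_s, strictly = TRUE))
    stop_petkin("frame starts must be strictly increasing",
                "petkin_invalid_schedule")
  ends <- frame_start_s + frame_duration_s
  n <- length(frame_start_s)
  if (n > 1L && any(ends[-n] > frame_start_s[-1L] + 1e-9))
    stop_petkin("frames must not overlap", "petkin_invalid_schedule")
  structure(
    data.frame(frame_start_s = as.numeric(frame_start_s),
               frame_duration_s = as.numeric(frame_duration_s)),
    class = c("frame_schedule", "data.frame")
  )
}

#' Default 28-frame, 60-minute acquisition schedule
#'
#' Ten frames of 30 s, five of 60 s, five of 120 s and eight of 300 s:
#' 28 frames spanning 0--3600 s, the protocol used for dynamic
#' small-animal receptor-tracer studies. The final frame covers the
#' 55--60 min window used for late-SUV readings.
#'
#' @return A [frame_schedule()] with 28 frames covering `[0, 3600]` s.
#' @examples
#' sched <- default_schedule()
#' nrow(sched)                       # 28
#' sum(sched$frame_duration_s)      # 3600
#' @export
default_schedule <- function() {
  dur <- c(rep(30, 10), rep(60, 5), rep(120, 5), rep(300, 8))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Frame midpoints in seconds
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame midpoint times (seconds).
#' @export
frame_mid_s <- function(schedule) {
  schedule$frame_start_s + schedule$frame_duration_s / 2
}

#' Time--activity curve
#'
#' Couples a [frame_schedule()] with one activity-concentration (or SUV)
#' value per frame. Values are frame averages, not instantaneous samples.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one value per frame; must be finite.
#' @param units unit label carried along for bookkeeping (default
#'   `"Bq/g"`; `"SUV"` after normalisation).
#' @return Object of class `tac` with fields `schedule`, `values`, `units`.
#' @export
tac <- function(schedule, values, units = "Bq/g") {
  if (!inherits(schedule, "frame_schedule"))
    schedule <- frame_schedule(schedule$frame_start_s, schedule$frame_duration_s)
  if (length(values) != nrow(schedule))
    stop_petkin("one value per frame required", "petkin_invalid_tac")
  if (any(!is.finite(values)))
    stop_petkin("TAC values must be finite", "petkin_invalid_tac")
  structure(list(schedule = schedule, values = as.numeric(values),
                 units = units),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  n <- nrow(x$schedule)
  span <- x$schedule$frame_start_s[n] + x$schedule$frame_duration_s[n]
  cat(sprintf("<tac> %d frames over %.0f s [%s]; range %.4g..%.4g\n",
              n, span, x$units, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.tac <- function(x) nrow(x$schedule)

same_schedule <- function(a, b, tol = 1e-6) {
  nrow(a) == nrow(b) &&
    max(abs(a$frame_start_s - b$frame_start_s)) < tol &&
    max(abs(a$frame_duration_s - b$frame_duration_s)) < tol
}

#' Read / write a time--activity curve as CSV
#'
#' The on-disk format is a three-column UTF-8 CSV with a header row:
#' `frame_start_s`, `frame_duration_s`, `activity_bq_per_ml`.
#'
#' @param path file path.
#' @param x a [tac()] object (for writing).
#' @return `read_tac_csv()` returns a [tac()]; `write_tac_csv()` returns
#'   `path` invisibly.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "activity_bq_per_ml")
  if (!all(need %in% names(df)))
    stop_petkin(sprintf("TAC CSV must have columns %s",
                        paste(need, collapse = ", ")),
                "petkin_invalid_tac")
  tac(frame_schedule(df$frame_start_s, df$frame_duration_s),
      df$activity_bq_per_ml)
}

#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(frame_start_s = x$schedule$frame_start_s,
                   frame_duration_s = x$schedule$frame_duration_s,
                   activity_bq_per_ml = x$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
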