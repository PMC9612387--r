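#' Frame schedule of a dynamic PET acquisition
#'
#' A `frame_schedule` records when each reconstructed frame of a dynamic
#' acquisition starts and how long it lasts, in seconds post-injection (p.i.).
#' Frames must be contiguous (each frame starts where the previous one ends),
#' non-overlapping, and start at 0 s.
#'
#' @param frame_durations_s Numeric vector of frame durations in seconds,
#'   all positive.
#' @param frame_starts_s Optional numeric vector of frame start times in
#'   seconds. Defaults to the cumulative sums implied by contiguous frames
#'   starting at 0; if supplied it is validated against that rule.
#' @return An object of class `frame_schedule`: a list with
#'   `frame_starts_s`, `frame_durations_s`.
#' @seealso [default_frame_schedule()], [frame_mid_times()]
#' @export
frame_schedule <- function(frame_durations_s, frame_starts_s = NULL) {
  frame_durations_s <- as.numeric(frame_durations_s)
  if (length(frame_durations_s) < 1L || any(!is.finite(frame_durations_s)) ||
      any(frame_durations_s <= 0)) {
    stop("frame durations must be finite and > 0")
  }
  implied <- cumsum(c(0, frame_durations_s[-length(frame_durations_s)]))
  if (is.null(frame_starts_s)) {
    frame_starts_s <- implied
  } else {
    frame_starts_s <- as.numeric(frame_starts_s)
    if (length(frame_starts_s) != length(frame_durations_s)) {
      stop("frame_starts_s and frame_durations_s must have equal length")
    }
    if (frame_starts_s[1] != 0) stop("first frame must start at 0 s")
    if (max(abs(frame_starts_s - implied)) > 1e-9) {
      stop("frames must be contiguous: start[i+1] = start[i] + duration[i]")
    }
  }
  structure(
    list(frame_starts_s = frame_starts_s, frame_durations_s = frame_durations_s),
    class = "frame_schedule"
  )
}

#' Standard 16-frame 0-40 min acquisition schedule
#'
#' The routine dynamic FET protocol: 7 x 10 s, 3 x 30 s, 1 x 2 min,
#' 3 x 5 min and 2 x 10 min frames, contiguous from injection. The printed
#' durations total 2380 s (39.67 min); the duration list is treated as
#' authoritative.
#'
#' @return A [frame_schedule()] with 16 frames.
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(10, 7), rep(30, 3), 120, rep(300, 3), rep(600, 2)))
}

#' Frame mid-times
#'
#' @param schedule A [frame_schedule()].
#' @param units `"min"` (default) or `"s"`.
#' @return Numeric vector of frame mid-times.
#' @export
frame_mid_times <- function(schedule, units = c("min", "s")) {
  stopifnot(inherits(schedule, "frame_schedule"))
  units <- match.arg(units)
  mid <- schedule$frame_starts_s + schedule$frame_durations_s / 2
  if (units == "min") mid / 60 else mid
}

#' Total acquisition span in seconds
#' @param schedule A [frame_schedule()].
#' @return End time of the last frame, seconds p.i.
#' @export
schedule_end <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  n <- length(schedule$frame_starts_s)
  schedule$frame_starts_s[n] + schedule$frame_durations_s[n]
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Dynamic PET frame schedule: %d frames, 0-%.4g min p.i.\n",
              length(x$frame_starts_s), schedule_end(x) / 60))
  cat("  durations (s): ", paste(x$frame_durations_s, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$frame_starts_s)
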