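#' Frame schedule for dynamic PET
#'
#' A frame schedule records the start time and duration of every
#' reconstructed frame of a dynamic PET acquisition, in seconds. Frames
#' must be contiguous (each frame starts where the previous one ends) and
#' the first frame must start at injection time (t = 0).
#'
#' @param starts Numeric vector of frame start times in seconds. Must be
#'   monotonically increasing with `starts[1] == 0`.
#' @param durations Numeric vector of frame durations in seconds, all
#'   positive, same length as `starts`.
#'
#' @return An object of class `frame_schedule`: a tibble with columns
#'   `frame`, `start`, `duration`, `mid` (frame mid-time, seconds).
#' @examples
#' sch <- frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' sch$mid
#' @export
frame_schedule <- function(starts, durations) {
  starts <- as.numeric(starts)
  durations <- as.numeric(durations)
  if (length(starts) != length(durations)) {
    stop("`starts` and `durations` must have the same length", call. = FALSE)
  }
  if (length(starts) == 0L) stop("schedule must have at least one frame", call. = FALSE)
  if (starts[1] != 0) stop("first frame must start at t = 0 s", call. = FALSE)
  if (any(durations <= 0)) stop("all frame durations must be positive", call. = FALSE)
  ends <- starts + durations
  if (length(starts) > 1L &&
      any(abs(starts[-1] - ends[-length(ends)]) > 1e-9)) {
    stop("frames must be contiguous: start[i+1] must equal start[i] + duration[i]",
         call. = FALSE)
  }
  out <- tibble::tibble(
    frame = seq_along(starts),
    start = starts,
    duration = durations,
    mid = starts + durations / 2
  )
  class(out) <- c("frame_schedule", class(out))
  out
}

#' Default dynamic PiB acquisition schedule
#'
#' The 70-min list-mode acquisition reconstructed as 12 x 5 s, 6 x 10 s,
#' 3 x 20 s, 4 x 30 s, 5 x 60 s, 4 x 5 min and 4 x 10 min frames
#' (38 frames). The first 21 frames cover exactly the initial 3 min used
#' for kinetic CBF estimation.
#'
#' @return A [frame_schedule()].
#' @examples
#' sch <- default_schedule()
#' nrow(sch)                       # 38
#' sum(sch$duration)               # 4200 s = 70 min
#' sch$start[22]                   # 180 s: first frame beyond the CBF window
#' @export
default_schedule <- function() {
  durations <- c(rep(5, 12), rep(10, 6), rep(20, 3), rep(30, 4),
                 rep(60, 5), rep(300, 4), rep(600, 4))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.0f s total>\n",
              nrow(x), sum(x$duration)))
  NextMethod()
}

schedule_total <- function(schedule) {
  utils::tail(schedule$start + schedule$duration, 1)
}

#' Frames whose mid-time falls inside a window
#'
#' @param schedule A [frame_schedule()].
#' @param window Numeric length-2, `[from, to)` in seconds.
#' @return Integer frame indices.
#' @keywords internal
frames_in_window <- function(schedule, window) {
  which(schedule$mid >= window[1] & schedule$mid < window[2])
}

schedule_to_json <- function(schedule, path, extra = list()) {
  payload <- c(list(FrameTimesStart = schedule$start,
                    FrameDuration = schedule$duration), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

schedule_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$FrameTimesStart) || is.null(payload$FrameDuration)) {
    stop("schedule sidecar must contain FrameTimesStart and FrameDuration",
         call. = FALSE)
  }
  frame_schedule(payload$FrameTimesStart, payload$FrameDuration)
}
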