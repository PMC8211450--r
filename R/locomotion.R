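# Motion-bout detection from body-center tracking: speed estimation,
# threshold/duration bout detection, per-minute distance traveled, and
# alignment of photometry to motion transitions.

track_frame_rate <- function(track) {
  fr <- attr(track, "frame_rate")
  if (!is.null(fr)) return(fr)
  dt <- diff(track$time_s)
  if (length(dt) < 1) abort("track needs at least 2 frames")
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-12) {
    abort("track frames are not uniformly spaced")
  }
  1 / mean(dt)
}

#' Body-center speed from a position track
#'
#' Central-difference speed (one-sided at the endpoints) with optional running
#' median smoothing to suppress frame-level tracking jitter.
#'
#' @param track a tibble with `time_s`, `x_mm`, `y_mm` (uniform frame rate).
#' @param smooth_frames odd window length for median smoothing; default 5;
#'   use 0 or 1 to disable.
#' @return A tibble with `time_s` and `speed_mm_s`.
#' @export
track_speed <- function(track, smooth_frames = 5) {
  n <- nrow(track)
  if (n < 2) abort("track needs at least 2 frames to estimate speed")
  fr <- track_frame_rate(track)
  x <- track$x_mm
  y <- track$y_mm
  v <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) * fr / 2
  }
  v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) * fr
  v[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) * fr
  if (smooth_frames >= 3) {
    if (smooth_frames %% 2 == 0) smooth_frames <- smooth_frames + 1
    v <- as.numeric(stats::runmed(v, smooth_frames, endrule = "keep"))
  }
  out <- tibble(time_s = track$time_s, speed_mm_s = v)
  attr(out, "frame_rate") <- fr
  out
}

#' Detect motion bouts from a speed series
#'
#' Movement is defined as the body center moving above the speed threshold
#' (default 30 mm/s) for at least the minimum duration (default 0.5 s). A bout
#' is a maximal run of supra-threshold frames; its onset is the first such
#' frame and its offset the last, and its duration is the number of frames
#' times the frame period. Raising the threshold can only shrink or remove
#' bouts, never create or lengthen them.
#'
#' @param speed a tibble from [track_speed()] (`time_s`, `speed_mm_s`).
#' @param threshold_mm_s speed threshold, mm/s; default 30.
#' @param min_duration_s minimum bout duration, seconds; default 0.5.
#' @return A tibble of class `motion_bouts`: `onset_s`, `offset_s`,
#'   `duration_s`, `peak_speed_mm_s`.
#' @export
detect_bouts <- function(speed, threshold_mm_s = 30, min_duration_s = 0.5) {
  fr <- attr(speed, "frame_rate")
  if (is.null(fr)) fr <- track_frame_rate(speed)
  above <- speed$speed_mm_s > threshold_mm_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths / fr >= min_duration_s - 1e-12)
  out <- tibble(
    onset_s = speed$time_s[starts[keep]],
    offset_s = speed$time_s[ends[keep]],
    duration_s = r$lengths[keep] / fr,
    peak_speed_mm_s = map_dbl(keep, function(k) {
      max(speed$speed_mm_s[starts[k]:ends[k]])
    })
  )
  attr(out, "threshold_mm_s") <- threshold_mm_s
  attr(out, "min_duration_s") <- min_duration_s
  class(out) <- c("motion_bouts", class(out))
  out
}

#' Distance traveled per minute
#'
#' Path length (sum of frame-to-frame displacements) within non-overlapping
#' 60-s windows; each step is attributed to the window containing its starting
#' frame. A trailing partial window is reported with `complete = FALSE`;
#' tracks shorter than one minute yield a single flagged partial value.
#'
#' @param track a tibble with `time_s`, `x_mm`, `y_mm`.
#' @return A tibble: `minute` (1-based), `distance_mm`, `complete`.
#' @export
distance_per_minute <- function(track) {
  n <- nrow(track)
  if (n < 2) abort("track needs at least 2 frames")
  step <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  win <- floor(track$time_s[-n] / 60)
  total <- tapply(step, win, sum)
  mins <- as.integer(names(total))
  dur <- max(track$time_s)
  dt <- (track$time_s[n] - track$time_s[1]) / (n - 1)
  out <- tibble(
    minute = mins + 1L,
    distance_mm = as.numeric(total),
    # a window is complete when the track reaches its end (up to one frame)
    complete = (mins + 1) * 60 <= dur + dt + 1e-9
  )
  if (dur < 60) {
    warn("track shorter than one minute: single partial window reported")
  }
  out
}

#' Align photometry to motion transitions
#'
#' Cuts peri-event dF/F segments around bout onsets or offsets, reusing the
#' trial-alignment machinery; rows are labeled with the event type.
#'
#' @param signal a dF/F `photometry_signal`.
#' @param bouts a `motion_bouts` tibble.
#' @param event `"onset"` or `"offset"`.
#' @param pre_s,post_s window, seconds.
#' @return An `aligned_traces` object (possibly with zero rows).
#' @export
align_to_bouts <- function(signal, bouts, event = c("onset", "offset"),
                           pre_s = 5, post_s = 8) {
  event <- match.arg(event)
  events <- tibble(
    onset_s = if (event == "onset") bouts$onset_s else bouts$offset_s,
    outcome = paste0("motion_", event)
  )
  al <- align_trials(signal, events, pre_s = pre_s, post_s = post_s)
  al
}
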