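#' Baseline-adjust a raw fluorescence signal to dF/F
#'
#' Normalizes raw fluorescence in non-overlapping windows as
#' `(signal - median(signal)) / median(signal)` computed per window, the
#' standard windowed-median dF/F used for fiber photometry. The final partial
#' window (and any signal shorter than one window) uses its own median, so the
#' formula stays local to each window. Within every full window the median of
#' the output is exactly zero, and the result is invariant to multiplying the
#' raw signal by any positive constant.
#'
#' @param signal a raw `photometry_signal` (see [photometry_signal()]).
#' @param window_s window length in seconds; default 100.
#' @return A `photometry_signal` with `kind = "dff"`, same length and rate.
#' @examples
#' raw <- photometry_signal(100 + rnorm(5000), sample_rate_hz = 50)
#' dff <- compute_dff(raw)
#' @export
compute_dff <- function(signal, window_s = 100) {
  if (signal_kind(signal) != "raw") {
    abort("compute_dff() expects a raw signal (kind = \"raw\")")
  }
  check_scalar_pos(window_s, "window_s")
  rate <- sample_rate(signal)
  x <- signal$value
  n <- length(x)
  wlen <- max(1L, as.integer(round(window_s * rate)))
  starts <- seq.int(1L, n, by = wlen)
  out <- numeric(n)
  for (k in seq_along(starts)) {
    idx <- starts[k]:min(starts[k] + wlen - 1L, n)
    m <- median(x[idx])
    if (!is.finite(m) || m <= 0) {
      abort(sprintf("window %d has non-positive median (%g); cannot form dF/F", k, m))
    }
    out[idx] <- (x[idx] - m) / m
  }
  photometry_signal(out, rate, t0_s = attr(signal, "t0_s") %||% 0, kind = "dff")
}

#' Downsample a photometry signal by block averaging
#'
#' Decimates by an integer factor using non-overlapping block means (the
#' factor is `sample_rate / target_rate_hz` and must be an integer). A trailing
#' partial block is averaged over the samples it contains. Block-mean
#' decimation preserves the overall mean exactly when the length divides the
#' factor.
#'
#' @param signal a `photometry_signal`.
#' @param target_rate_hz target sampling rate in Hz; must divide the current
#'   rate.
#' @return A `photometry_signal` at `target_rate_hz`, same `kind`.
#' @export
downsample_signal <- function(signal, target_rate_hz) {
  check_scalar_pos(target_rate_hz, "target_rate_hz")
  rate <- sample_rate(signal)
  factor <- rate / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    abort(sprintf(
      "sample rate %g Hz is not an integer multiple of target %g Hz",
      rate, target_rate_hz
    ))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(signal)
  x <- signal$value
  grp <- (seq_along(x) - 1L) %/% factor
  y <- as.numeric(tapply(x, grp, mean))
  photometry_signal(y, target_rate_hz,
    t0_s = attr(signal, "t0_s") %||% 0,
    kind = signal_kind(signal)
  )
}

#' Align dF/F segments to trial events
#'
#' Cuts a fixed peri-event window around each trial onset and stacks the
#' segments on a common relative time grid. The grid is half-open
#' `[-pre_s, post_s)` at the signal's sampling rate, with the onset sample
#' included on the post side (relative time 0). Trials whose window falls
#' outside the recording are skipped with a warning and recorded in the
#' `excluded` attribute.
#'
#' @param signal a dF/F `photometry_signal`.
#' @param trials a trial table with at least `onset_s`; columns `outcome`,
#'   `shock_duration_s`, `latency_s`, `trial_index`, `subject`, `condition` are
#'   carried through when present.
#' @param pre_s,post_s seconds before/after the event; defaults 5 and 8,
#'   giving the standard 13-s peri-shock window.
#' @param event_col name of the column holding event times; default `onset_s`.
#' @return An `aligned_traces` object: a trials-by-samples matrix plus the
#'   relative time grid and per-trial metadata. Use [generics::tidy()] for a
#'   long tibble.
#' @export
align_trials <- function(signal, trials, pre_s = 5, post_s = 8, event_col = "onset_s") {
  if (signal_kind(signal) != "dff") {
    warn("align_trials() called on a non-dF/F signal; aligning raw values")
  }
  check_scalar_pos(pre_s, "pre_s")
  check_scalar_pos(post_s, "post_s")
  if (!event_col %in% names(trials)) {
    abort(sprintf("trial table has no `%s` column", event_col))
  }
  rate <- sample_rate(signal)
  t0 <- attr(signal, "t0_s") %||% 0
  n_pre <- as.integer(round(pre_s * rate))
  n_post <- as.integer(round(post_s * rate))
  width <- n_pre + n_post
  grid <- (seq_len(width) - 1L - n_pre) / rate
  x <- signal$value
  n <- length(x)

  trials <- as_tibble(trials)
  onsets <- trials[[event_col]]
  onset_idx <- as.integer(round((onsets - t0) * rate)) + 1L
  lo <- onset_idx - n_pre
  hi <- onset_idx + n_post - 1L
  ok <- lo >= 1L & hi <= n
  if (any(!ok)) {
    warn(sprintf(
      "%d trial(s) excluded from alignment: peri-event window outside recording",
      sum(!ok)
    ))
  }
  keep <- which(ok)
  traces <- matrix(NA_real_, nrow = length(keep), ncol = width)
  for (i in seq_along(keep)) {
    traces[i, ] <- x[lo[keep[i]]:hi[keep[i]]]
  }
  meta <- trials[keep, , drop = FALSE]
  if (!"outcome" %in% names(meta)) meta$outcome <- NA_character_
  structure(
    list(
      traces = traces,
      time_s = grid,
      trials = meta,
      sample_rate_hz = rate,
      pre_s = pre_s,
      post_s = post_s,
      excluded = trials[!ok, , drop = FALSE]
    ),
    class = "aligned_traces"
  )
}

#' @export
print.aligned_traces <- function(x, ...) {
  cat(sprintf(
    "<aligned_traces: %d trials x %d samples, [%g, %g) s @ %g Hz>\n",
    nrow(x$traces), ncol(x$traces), -x$pre_s, x$post_s, x$sample_rate_hz
  ))
  if (nrow(x$trials) > 0 && !all(is.na(x$trials$outcome))) {
    print(table(x$trials$outcome))
  }
  invisible(x)
}

#' @export
dim.aligned_traces <- function(x) dim(x$traces)
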