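#' Construct a uniformly sampled photometry signal
#'
#' A photometry signal is a tibble with columns `time_s` and `value` plus
#' metadata attributes (`sample_rate_hz`, `t0_s`, `kind`). `kind` records
#' whether the samples are raw fluorescence (arbitrary units) or
#' baseline-adjusted dF/F (dimensionless).
#'
#' @param value numeric vector of samples (no missing values).
#' @param sample_rate_hz sampling rate in Hz.
#' @param t0_s absolute time of the first sample, seconds.
#' @param kind `"raw"` or `"dff"`.
#' @return A tibble of class `photometry_signal` with columns `time_s`, `value`.
#' @examples
#' sig <- photometry_signal(rnorm(1000), sample_rate_hz = 100)
#' sample_rate(sig)
#' @export
photometry_signal <- function(value, sample_rate_hz, t0_s = 0, kind = c("raw", "dff")) {
  kind <- match.arg(kind)
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  value <- as.double(value)
  if (anyNA(value)) abort("photometry signal must not contain missing samples")
  out <- tibble(
    time_s = t0_s + (seq_along(value) - 1) / sample_rate_hz,
    value = value
  )
  attr(out, "sample_rate_hz") <- as.double(sample_rate_hz)
  attr(out, "t0_s") <- as.double(t0_s)
  attr(out, "kind") <- kind
  class(out) <- c("photometry_signal", class(tibble()))
  out
}

#' @rdname photometry_signal
#' @param x a `photometry_signal`.
#' @export
sample_rate <- function(x) {
  r <- attr(x, "sample_rate_hz")
  if (is.null(r)) abort("not a photometry_signal: missing sample_rate_hz")
  r
}

#' @rdname photometry_signal
#' @export
signal_kind <- function(x) attr(x, "kind") %||% "raw"

#' @export
print.photometry_signal <- function(x, ...) {
  cat(sprintf(
    "<photometry_signal: %d samples @ %g Hz, kind = %s, %.1f s>\n",
    nrow(x), sample_rate(x), signal_kind(x), nrow(x) / sample_rate(x)
  ))
  NextMethod()
}
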