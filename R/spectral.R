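# Welch power spectral density for spontaneous calcium traces: Hann-windowed,
# 50%-overlapping averaged periodograms, summarized by max power and the
# frequency at max power (DC excluded), plus paired before/after deltas.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Welch power spectral density
#'
#' Splits the trace into overlapping segments, applies a Hann window to each,
#' averages the one-sided modified periodograms, and reports the density in
#' power per Hz. Each segment's mean is removed before windowing. The maximum
#' power and its frequency are found excluding the DC bin, since
#' baseline-adjusted traces can retain a residual offset that would otherwise
#' dominate.
#'
#' @param x numeric trace (baseline-adjusted), or a `photometry_signal` (in
#'   which case `sample_rate_hz` is taken from it).
#' @param sample_rate_hz sampling rate, Hz.
#' @param segment_length samples per segment; default 256 (~21 s at 12 Hz,
#'   frequency resolution ~0.047 Hz).
#' @param overlap fractional overlap between segments; default 0.5.
#' @param demean remove each segment's mean before windowing; default TRUE.
#' @return A tibble of class `psd_result` with columns `frequency_hz`,
#'   `power`, and attributes `max_power`, `freq_at_max_power_hz`,
#'   `segment_length`, `overlap`, `sample_rate_hz`, `n_segments`. Use
#'   `glance()` for a one-row summary.
#' @export
welch_psd <- function(x, sample_rate_hz = NULL, segment_length = 256,
                      overlap = 0.5, demean = TRUE) {
  if (inherits(x, "photometry_signal")) {
    sample_rate_hz <- sample_rate(x)
    x <- x$value
  }
  if (is.null(sample_rate_hz)) abort("`sample_rate_hz` is required for a bare vector")
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  n <- length(x)
  nseg <- as.integer(segment_length)
  if (nseg < 8) abort("`segment_length` must be at least 8 samples")
  if (n < nseg) {
    abort(sprintf(
      "trace (%d samples) is shorter than one segment (%d); use a shorter segment_length",
      n, nseg
    ))
  }
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  w <- hann_window(nseg)
  scale <- sample_rate_hz * sum(w^2)
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(nfreq)]
    p <- (Mod(X)^2) / scale
    # one-sided: double everything except DC (and Nyquist when nseg is even)
    mult <- rep(2, nfreq)
    mult[1] <- 1
    if (nseg %% 2 == 0) mult[nfreq] <- 1
    acc <- acc + p * mult
  }
  pxx <- acc / length(starts)
  freq <- (seq_len(nfreq) - 1) * sample_rate_hz / nseg
  imax <- which.max(pxx[-1]) + 1L
  out <- tibble(frequency_hz = freq, power = pxx)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "segment_length") <- nseg
  attr(out, "overlap") <- overlap
  attr(out, "n_segments") <- length(starts)
  attr(out, "max_power") <- pxx[imax]
  attr(out, "freq_at_max_power_hz") <- freq[imax]
  class(out) <- c("psd_result", class(out))
  out
}

#' @rdname welch_psd
#' @export
max_power <- function(x) attr(x, "max_power")

#' @rdname welch_psd
#' @export
freq_at_max_power <- function(x) attr(x, "freq_at_max_power_hz")

#' Paired before/after PSD change
#'
#' Per-ROI differences (after minus before) in max power and in the frequency
#' at max power, for paired recordings analyzed with identical Welch settings.
#'
#' @param before,after `psd_result` objects with matching sample rate,
#'   segment length and overlap.
#' @return A one-row tibble: `delta_max_power`, `delta_freq_at_max_hz`.
#' @export
psd_delta <- function(before, after) {
  for (a in c("sample_rate_hz", "segment_length", "overlap")) {
    if (!isTRUE(all.equal(attr(before, a), attr(after, a)))) {
      abort(sprintf("PSD settings mismatch: `%s` differs between before and after", a))
    }
  }
  tibble(
    delta_max_power = max_power(after) - max_power(before),
    delta_freq_at_max_hz = freq_at_max_power(after) - freq_at_max_power(before)
  )
}
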