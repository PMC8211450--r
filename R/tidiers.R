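# broom-style tidiers for the package's result classes.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.aligned_traces <- function(x, ...) {
  n <- nrow(x$traces)
  if (n == 0) {
    return(tibble(trial = integer(), outcome = character(),
                  time_s = numeric(), dff = numeric()))
  }
  tibble(
    trial = rep(seq_len(n), each = ncol(x$traces)),
    outcome = rep(x$trials$outcome, each = ncol(x$traces)),
    time_s = rep(x$time_s, times = n),
    dff = as.vector(t(x$traces))
  )
}

#' @export
glance.aligned_traces <- function(x, ...) {
  tibble(
    n_trials = nrow(x$traces),
    n_samples = ncol(x$traces),
    sample_rate_hz = x$sample_rate_hz,
    pre_s = x$pre_s,
    post_s = x$post_s,
    n_excluded = nrow(x$excluded)
  )
}

#' @export
tidy.transition_model <- function(x, ...) {
  tibble(
    from = rep(rownames(x$probs), times = 3),
    to = rep(colnames(x$probs), each = 3),
    count = as.integer(x$counts),
    probability = as.vector(x$probs),
    probability_by_occurrence = as.vector(x$probs_by_occurrence)
  )
}

#' @export
glance.transition_model <- function(x, ...) {
  tibble(
    n_sequences = x$n_sequences,
    n_transitions = sum(x$counts),
    n_undefined_rows = sum(rowSums(x$counts) == 0)
  )
}

#' @export
tidy.failure_fit <- function(x, ...) x$histogram

#' @export
glance.failure_fit <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n = x$n, bin_width = x$bin_width)
}

#' @export
glance.psd_result <- function(x, ...) {
  tibble(
    max_power = max_power(x),
    freq_at_max_power_hz = freq_at_max_power(x),
    sample_rate_hz = attr(x, "sample_rate_hz"),
    segment_length = attr(x, "segment_length"),
    overlap = attr(x, "overlap"),
    n_segments = attr(x, "n_segments")
  )
}

#' @export
glance.correlation_result <- function(x, ...) as_tibble(unclass(x))

#' @export
tidy.recovery_report <- function(x, ...) x$subjects

#' @export
glance.recovery_report <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$subjects),
    designed_slope = x$designed_slope,
    recovered_slope = x$recovered_slope,
    designed_r2 = x$designed_r2,
    recovered_r2 = x$recovered_r2,
    r = x$correlation$r
  )
}
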