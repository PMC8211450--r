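# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_tile geom_col
#'   geom_ribbon geom_point geom_vline geom_function labs facet_wrap
#'   scale_fill_gradient2 theme_minimal stat_summary
#' @export
ggplot2::autoplot

#' @export
autoplot.aligned_traces <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time_s, y = .data$dff, color = .data$outcome)) +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    stat_summary(fun = mean, geom = "line", linewidth = 0.8) +
    labs(x = "time from shock onset (s)", y = "dF/F",
         title = "Outcome-specific mean transients") +
    theme_minimal()
}

#' @export
autoplot.outcome_means <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$mean_dff, color = .data$outcome)) +
    geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    geom_line(linewidth = 0.8) +
    labs(x = "time from shock onset (s)", y = "mean dF/F") +
    theme_minimal()
}

#' @export
autoplot.transition_model <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$probability)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "steelblue4", limits = c(0, 1)) +
    labs(x = "to outcome", y = "from outcome", fill = "P") +
    theme_minimal()
}

#' @export
autoplot.psd_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df[-1, ], aes(x = .data$frequency_hz, y = .data$power)) +
    geom_line() +
    geom_vline(xintercept = freq_at_max_power(object),
               linetype = "dashed", color = "firebrick") +
    labs(x = "frequency (Hz)", y = "power spectral density",
         title = sprintf("Welch PSD (peak %.3g at %.3g Hz)",
                         max_power(object), freq_at_max_power(object))) +
    theme_minimal()
}

#' @export
autoplot.failure_fit <- function(object, ...) {
  mu <- object$mu
  sigma <- object$sigma
  ggplot(object$histogram, aes(x = (.data$bin_left + .data$bin_right) / 2,
                               y = .data$density)) +
    geom_col(width = object$bin_width, fill = "grey75", color = "grey40") +
    geom_function(fun = function(x) stats::dnorm(x, mu, sigma), color = "firebrick") +
    labs(x = "% failures", y = "density",
         title = sprintf("Gaussian MLE: mu = %.1f, sigma = %.1f", mu, sigma)) +
    theme_minimal()
}

#' Learning curves for a cohort trial table
#'
#' One cumulative escape-minus-failure trajectory per subject, faceted by
#' condition.
#'
#' @param trials a trial table with `subject`, `condition`, `outcome` columns.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(trials) {
  curves <- trials |>
    group_by(.data$subject, .data$condition) |>
    group_modify(~ learning_curve(.x$outcome)) |>
    ungroup()
  ggplot(curves, aes(x = .data$trial_index, y = .data$value,
                     color = .data$subject)) +
    geom_line() +
    facet_wrap(~condition) +
    labs(x = "trial", y = "cumulative escapes - failures",
         title = "Learning curves") +
    theme_minimal()
}
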