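# Cohort-level association analyses: Pearson correlation between per-subject
# statistics (trace distance vs. failure percentage), and the end-to-end
# parameter-recovery harness tying generator -> preprocessing -> transients ->
# behavior -> correlation together.

#' Pearson correlation with least-squares line
#'
#' Pearson r, r-squared and the simple least-squares line between two
#' per-subject variables. Significance of r is reported through the standard
#' t transform for reference.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite values.
#' @return An object of class `correlation_result` (a one-row tibble):
#'   `r`, `r_squared`, `slope`, `intercept`, `n`, `t_statistic`.
#' @export
correlate_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("correlate_pearson() needs at least 3 complete pairs")
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    warn("zero variance in x or y: correlation undefined")
    out <- tibble(r = NA_real_, r_squared = NA_real_, slope = NA_real_,
                  intercept = NA_real_, n = n, t_statistic = NA_real_)
  } else {
    r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
    slope <- r * sy / sx
    out <- tibble(
      r = r, r_squared = r^2, slope = slope,
      intercept = mean(y) - slope * mean(x), n = n,
      t_statistic = r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    )
  }
  class(out) <- c("correlation_result", class(out))
  out
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a synthetic cohort with a known coupling between each subject's
#' baseline escape-vs-failure trace distance and their failure fraction under
#' learned helplessness, then runs the full measurement pipeline (windowed
#' dF/F, downsampling, trial alignment, outcome means, trace distance,
#' failure statistics) and correlates the *measured* baseline distance with
#' the *observed* LH failure fraction. The report compares the designed
#' coupling (slope, and the R-squared implied by the realized ground truth
#' plus trial-count binomial noise) with what the pipeline recovers.
#'
#' @param config a `cohort_config` with nonzero `coupling_slope`; only the
#'   `baseline` and `LH` conditions are simulated.
#' @param n_subjects overrides `config$n_subjects` if given.
#' @param seed overrides `config$seed` if given.
#' @param exact_fractions if TRUE, bypass outcome sampling noise and score
#'   each subject's failure fraction at its designed probability (the
#'   noiseless limit used to verify exact slope recovery).
#' @return An object of class `recovery_report`: per-subject tibble plus
#'   designed and recovered coupling summaries (see `glance()`).
#' @export
recovery_experiment <- function(config = cohort_config(), n_subjects = NULL,
                                seed = NULL, exact_fractions = FALSE) {
  config <- validate_cohort_config(config)
  if (!is.null(n_subjects)) config$n_subjects <- n_subjects
  if (!is.null(seed)) config$seed <- seed
  config$conditions <- intersect(config$conditions, c("baseline", "LH"))
  if (!all(c("baseline", "LH") %in% config$conditions)) {
    abort("recovery_experiment() needs both `baseline` and `LH` conditions configured")
  }
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sub <- simulate_subject(config, i)
    # measured baseline trace distance through the full photometry path
    dff <- compute_dff(sub$signals[["baseline"]], window_s = 100)
    dff <- downsample_signal(dff, config$timelocked_rate_hz)
    trb <- sub$trials[sub$trials$condition == "baseline", ]
    al <- align_trials(dff, trb, pre_s = config$pre_s, post_s = config$post_s)
    mm <- outcome_mean_traces(al)
    d_hat <- if (all(c("escape", "failure") %in% mm$outcome)) {
      trace_distance(mm)
    } else NA_real_
    # observed LH failure fraction
    trl <- sub$trials[sub$trials$condition == "LH", ]
    fs <- failure_stats(trl)
    frac <- fs$pct_failures / 100
    p_design <- sub$truth$expected_failure_prob[["LH"]]
    if (exact_fractions) frac <- p_design
    rows[[i]] <- tibble(
      subject = sub$truth$subject,
      gain = sub$truth$gain,
      true_distance = sub$truth$true_distance,
      measured_distance = d_hat,
      designed_failure_prob = p_design,
      observed_failure_fraction = frac,
      n_nonspontaneous = fs$n_escape + fs$n_failure
    )
  }
  subjects <- list_rbind(rows)
  cc <- correlate_pearson(subjects$measured_distance, subjects$observed_failure_fraction)
  # Designed R^2: coupling signal variance over signal + binomial trial noise,
  # from the realized ground truth of this cohort.
  sig_var <- var(subjects$designed_failure_prob)
  noise_var <- if (exact_fractions) 0 else {
    mean(subjects$designed_failure_prob * (1 - subjects$designed_failure_prob) /
           pmax(subjects$n_nonspontaneous, 1))
  }
  designed_r2 <- if (sig_var + noise_var == 0) NA_real_ else sig_var / (sig_var + noise_var)
  structure(
    list(
      subjects = subjects,
      correlation = cc,
      designed_slope = config$coupling_slope,
      recovered_slope = cc$slope,
      designed_r2 = designed_r2,
      recovered_r2 = cc$r_squared,
      config = config
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<recovery_report: n = %d subjects>\n",
      "  designed slope %.4g, recovered %.4g\n",
      "  designed R^2 %.3f, recovered %.3f (r = %.3f)\n"
    ),
    nrow(x$subjects), x$designed_slope, x$recovered_slope,
    x$designed_r2, x$recovered_r2, x$correlation$r
  ))
  invisible(x)
}

#' Coupling slope achieving a target designed R-squared
#'
#' For a given cohort configuration, computes the coupling slope whose
#' signal variance (slope^2 times the variance of true baseline trace
#' distance over the subject-gain distribution) against binomial trial noise
#' yields the requested designed R-squared for the distance-vs-failure
#' correlation. Negative by convention: larger baseline separation predicts
#' fewer failures.
#'
#' @param config a `cohort_config`.
#' @param target_r2 designed coefficient of determination, in (0, 1).
#' @param n_grid quadrature points over the gain range; default 201.
#' @return A single negative number, in failure-fraction per unit distance.
#' @export
coupling_for_target_r2 <- function(config, target_r2, n_grid = 201) {
  config <- validate_cohort_config(config)
  stopifnot(target_r2 > 0, target_r2 < 1)
  g <- seq(config$subject_gain_range[1], config$subject_gain_range[2],
           length.out = n_grid)
  d <- map_dbl(g, function(gi) true_trace_distance(config, gi))
  var_d <- mean((d - mean(d))^2)
  if (var_d <= 0) abort("gain range induces no variance in trace distance")
  m <- config$transition_matrices[["LH"]]
  p0 <- stationary_failure_prob(m)
  p_spont <- mean(m[, "spontaneous"])
  n_ns <- config$trials_per_session * (1 - p_spont)
  noise_var <- p0 * (1 - p0) / n_ns
  -sqrt(target_r2 / (1 - target_r2) * noise_var / var_d)
}
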