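# Behavioral summaries: failure percentages and escape latencies, learning
# curves, three-state transition models with a Frobenius similarity score,
# run-length statistics, and Gaussian fits to cohort failure distributions.

#' Failure percentage and mean escape latency
#'
#' The failure percentage is `failures / (failures + escapes) * 100`;
#' spontaneous (pre-shock) shuttles are neither escapes nor failures of the
#' shock trial and are excluded from the denominator. The mean latency is
#' taken over all non-spontaneous trials with failures contributing the cap
#' value (the shock duration: 10 s in the strong paradigm, 3 s in the weak
#' one), the convention under which failures are scored at full shock length.
#'
#' @param trials a trial table with columns `outcome` and `latency_s`;
#'   dplyr groups are respected, so group by `subject` and/or `condition`
#'   first for per-group summaries.
#' @return A tibble with `n_escape`, `n_failure`, `n_spontaneous`,
#'   `pct_failures`, `mean_latency_s` (one row per group).
#' @export
failure_stats <- function(trials) {
  check_outcomes(trials$outcome)
  summarise(
    trials,
    n_escape = sum(.data$outcome == "escape"),
    n_failure = sum(.data$outcome == "failure"),
    n_spontaneous = sum(.data$outcome == "spontaneous"),
    pct_failures = if (.data$n_escape[1] + .data$n_failure[1] == 0) NA_real_ else
      100 * .data$n_failure[1] / (.data$n_escape[1] + .data$n_failure[1]),
    mean_latency_s = if (.data$n_escape[1] + .data$n_failure[1] == 0) NA_real_ else
      mean(.data$latency_s[.data$outcome != "spontaneous"]),
    .groups = "drop"
  )
}

#' Cumulative learning curve over trials
#'
#' Starting at zero, the trajectory increments by one on each escape trial,
#' decrements by one on each failure, and stays constant on spontaneous
#' transitions; its final value is `#escapes - #failures`.
#'
#' @param outcomes an ordered character vector of outcomes, or a trial table
#'   with an `outcome` column (assumed already in trial order).
#' @return A tibble with `trial_index` and `value`.
#' @export
learning_curve <- function(outcomes) {
  if (is.data.frame(outcomes)) outcomes <- outcomes$outcome
  outcomes <- check_outcomes(outcomes)
  step <- c(escape = 1, failure = -1, spontaneous = 0)[outcomes]
  tibble(trial_index = seq_along(outcomes), value = cumsum(unname(step)))
}

as_sequence_list <- function(x) {
  if (is.data.frame(x)) {
    key <- interaction(
      x[["subject"]] %||% "s1",
      x[["condition"]] %||% "c1",
      drop = TRUE
    )
    x <- split(as.character(x$outcome), key)
  }
  if (!is.list(x)) x <- list(x)
  lapply(x, check_outcomes)
}

#' Three-state behavioral transition model
#'
#' Counts the occurrences of every two-response sequence (escape, failure,
#' spontaneous) pooled across animals, then divides each row by that state's
#' total number of outgoing transitions, giving a 3x3 row-stochastic matrix.
#' Each animal's final trial contributes no outgoing transition and sequences
#' never concatenate across animals or sessions. Rows with no outgoing
#' transitions are left undefined (`NA`). The alternative normalization by
#' total state occurrences (including terminal ones) is also computed and kept
#' in `probs_by_occurrence`.
#'
#' @param sequences a list of per-animal outcome sequences, a single character
#'   vector, or a trial table (split by `subject` x `condition`).
#' @return An object of class `transition_model` with elements `counts`,
#'   `probs`, `probs_by_occurrence`, `n_sequences`.
#' @export
transition_model <- function(sequences) {
  seqs <- as_sequence_list(sequences)
  seqs <- seqs[lengths(seqs) > 0]
  if (length(seqs) == 0) abort("transition_model() needs at least one non-empty sequence")
  counts <- matrix(0L, 3, 3, dimnames = list(OUTCOME_LEVELS, OUTCOME_LEVELS))
  occ <- setNames(integer(3), OUTCOME_LEVELS)
  for (s in seqs) {
    occ_s <- table(factor(s, levels = OUTCOME_LEVELS))
    occ <- occ + as.integer(occ_s)
    if (length(s) < 2) next
    from <- s[-length(s)]
    to <- s[-1]
    tab <- table(factor(from, levels = OUTCOME_LEVELS), factor(to, levels = OUTCOME_LEVELS))
    counts <- counts + matrix(as.integer(tab), 3, 3)
  }
  if (sum(counts) == 0) abort("no transitions found in the input sequences")
  out_trans <- rowSums(counts)
  probs <- counts / ifelse(out_trans > 0, out_trans, NA_real_)
  probs_occ <- counts / ifelse(occ > 0, occ, NA_real_)
  structure(
    list(
      counts = counts,
      probs = probs,
      probs_by_occurrence = probs_occ,
      n_sequences = length(seqs)
    ),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, digits = 3, ...) {
  cat(sprintf("<transition_model: %d sequence(s), %d transitions>\n",
              x$n_sequences, sum(x$counts)))
  print(round(x$probs, digits))
  invisible(x)
}

#' Similarity between two transition models
#'
#' One minus the Frobenius norm (the Euclidean norm of a matrix) of the
#' difference between the two probability matrices:
#' `1 - sqrt(sum((a - b)^2))`. Identical models score 1; the score is
#' symmetric and can be negative (no clipping is applied).
#'
#' @param a,b `transition_model` objects (or bare 3x3 probability matrices)
#'   with all rows defined.
#' @return A single number `<= 1`.
#' @export
model_similarity <- function(a, b) {
  pa <- if (inherits(a, "transition_model")) a$probs else a
  pb <- if (inherits(b, "transition_model")) b$probs else b
  for (nm in c("a", "b")) {
    p <- if (nm == "a") pa else pb
    if (!is.matrix(p) || !all(dim(p) == c(3, 3))) {
      abort(sprintf("`%s` must be a 3x3 probability matrix or transition_model", nm))
    }
    bad <- rownames(p)[apply(p, 1, function(r) any(is.na(r)))]
    if (is.null(rownames(p))) bad <- which(apply(p, 1, anyNA))
    if (length(bad) > 0) {
      abort(sprintf("`%s` has undefined row(s): %s", nm, paste(bad, collapse = ", ")))
    }
  }
  1 - sqrt(sum((pa - pb)^2))
}

#' Run-length statistics of an outcome sequence
#'
#' For each outcome label reports the probability of a successive repeat
#' (`P(X -> X)` estimated from this sequence's transitions), and the mean and
#' maximum length of maximal runs of that label.
#'
#' @param outcomes an ordered outcome sequence (or trial table).
#' @return A tibble with one row per outcome label present or possible:
#'   `outcome`, `p_repeat`, `n_runs`, `mean_run`, `max_run`.
#' @export
run_length_stats <- function(outcomes) {
  if (is.data.frame(outcomes)) outcomes <- outcomes$outcome
  outcomes <- check_outcomes(outcomes)
  if (length(outcomes) == 0) abort("empty outcome sequence")
  r <- rle(outcomes)
  from <- outcomes[-length(outcomes)]
  to <- outcomes[-1]
  map(OUTCOME_LEVELS, function(o) {
    lens <- r$lengths[r$values == o]
    n_out <- sum(from == o)
    tibble(
      outcome = o,
      p_repeat = if (n_out > 0) sum(from == o & to == o) / n_out else NA_real_,
      n_runs = length(lens),
      mean_run = if (length(lens) > 0) mean(lens) else NA_real_,
      max_run = if (length(lens) > 0) max(lens) else NA_real_
    )
  }) |> list_rbind()
}

#' Gaussian fit to a cohort's failure-percentage distribution
#'
#' Maximum-likelihood Normal fit on the raw per-animal failure percentages
#' (`mu` = sample mean, `sigma` = sqrt of the mean squared deviation, the MLE
#' with denominator n), plus a density histogram with fixed bin width on
#' [0, 100] for display.
#'
#' @param percent_failures per-animal failure percentages (0-100); at least 3.
#' @param bin_width histogram bin width; default 4.
#' @return An object of class `failure_fit` with `mu`, `sigma`, `n`,
#'   `histogram` (tibble: `bin_left`, `bin_right`, `count`, `density`).
#' @export
fit_failure_distribution <- function(percent_failures, bin_width = 4) {
  x <- percent_failures[is.finite(percent_failures)]
  if (length(x) < 3) abort("need at least 3 finite failure percentages to fit")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  breaks <- seq(0, ceiling(max(100, max(x)) / bin_width) * bin_width, by = bin_width)
  cnt <- as.integer(table(cut(x, breaks, include.lowest = TRUE, right = FALSE)))
  hist_tbl <- tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    count = cnt,
    density = cnt / (length(x) * bin_width)
  )
  structure(
    list(mu = mu, sigma = sigma, n = length(x), bin_width = bin_width,
         values = x, histogram = hist_tbl),
    class = "failure_fit"
  )
}

#' @export
print.failure_fit <- function(x, ...) {
  cat(sprintf(
    "<failure_fit: Normal MLE mu = %.2f, sigma = %.2f (n = %d, bin width %g)>\n",
    x$mu, x$sigma, x$n, x$bin_width
  ))
  invisible(x)
}
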