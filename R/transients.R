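# Transient quantification: baseline statistics, signed peaks with omission
# rules, trapezoidal AUC, outcome-specific mean traces, and the
# escape-vs-failure trace distance.

BASELINE_WINDOW_S <- 5

baseline_idx <- function(time_s, pre_s = BASELINE_WINDOW_S) {
  if (min(time_s) > -pre_s + 1e-9) {
    abort(sprintf("aligned grid does not cover the [-%g, 0) s baseline segment", pre_s))
  }
  idx <- which(time_s >= -pre_s - 1e-12 & time_s < -1e-12)
  if (length(idx) < 2) {
    abort(sprintf("aligned grid does not cover the [-%g, 0) s baseline segment", pre_s))
  }
  idx
}

#' Pre-event baseline statistics for aligned traces
#'
#' The baseline is the mean dF/F of the 5-s segment immediately before the
#' event onset; its standard deviation (sample SD) feeds the peak omission
#' rule.
#'
#' @param aligned an `aligned_traces` object covering at least `[-5, 0)` s.
#' @return A tibble with one row per trial: `trial`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
baseline_stats <- function(aligned) {
  idx <- baseline_idx(aligned$time_s)
  seg <- aligned$traces[, idx, drop = FALSE]
  tibble(
    trial = seq_len(nrow(seg)),
    baseline_mean = rowMeans(seg),
    baseline_sd = apply(seg, 1, sd)
  )
}

# Omission decision for one peak amplitude (baseline-referenced).
# A peak is omitted if below 5% of the trace's min-to-max range or below three
# baseline SDs; a flat trace omits everything.
omission_reason <- function(amplitude, trace_range, baseline_sd) {
  if (trace_range <= 0) return("zero range")
  reasons <- character(0)
  if (abs(amplitude) < 0.05 * trace_range) reasons <- c(reasons, "below 5% of range")
  if (abs(amplitude) < 3 * baseline_sd) reasons <- c(reasons, "below 3 SD of baseline")
  if (length(reasons) == 0) NA_character_ else paste(reasons, collapse = "; ")
}

#' Signed peak, AUC and latency metrics for aligned transients
#'
#' For each aligned trial, peaks are measured relative to the pre-event
#' baseline mean in two windows: *during* the shock (`[0, d]` where `d` is the
#' shock duration, or the recorded escape time for escape trials, whose shock
#' terminates at the shuttle) and *after* it (`(d, post_limit_s]`). Each window
#' reports the positive peak (maximum) and negative peak (minimum); a peak is
#' flagged omitted when its amplitude is less than 5% of the trace's
#' min-to-max range or less than three times the baseline-period SD. Positive
#' and negative AUC are trapezoidal integrals of the baseline-subtracted
#' trace's positive and negative parts in the same windows. Latency to peak is
#' the time from onset to the maximum value within `post_limit_s` of onset
#' (earliest sample on ties).
#'
#' @param aligned an `aligned_traces` object with `shock_duration_s` (and,
#'   for escape trials, `latency_s`) in its trial metadata.
#' @param post_limit_s end of the analysis horizon after onset, seconds
#'   (default 8).
#' @return A tibble with one row per trial: baseline statistics, the four
#'   signed peaks with per-peak omission flags and reasons, the four signed
#'   AUCs, and `latency_to_peak_s`.
#' @export
transient_metrics <- function(aligned, post_limit_s = 8) {
  grid <- aligned$time_s
  if (max(grid) < post_limit_s - 1 / aligned$sample_rate_hz - 1e-9) {
    abort(sprintf("aligned grid must cover [0, %g] s after onset", post_limit_s))
  }
  meta <- aligned$trials
  if (!"shock_duration_s" %in% names(meta)) {
    abort("trial metadata must include `shock_duration_s`")
  }
  bl <- baseline_stats(aligned)
  n <- nrow(aligned$traces)
  rows <- vector("list", n)
  lat_idx <- which(grid >= -1e-12 & grid <= post_limit_s + 1e-12)
  for (i in seq_len(n)) {
    tr <- aligned$traces[i, ]
    bmean <- bl$baseline_mean[i]
    bsd <- bl$baseline_sd[i]
    rng <- max(tr) - min(tr)
    outcome <- meta$outcome[i] %||% NA_character_
    dur <- meta$shock_duration_s[i]
    if (identical(outcome, "escape") && "latency_s" %in% names(meta) &&
        is.finite(meta$latency_s[i])) {
      dur <- meta$latency_s[i]
    }
    during <- which(grid >= -1e-12 & grid <= dur + 1e-12)
    after <- which(grid > dur + 1e-12 & grid <= post_limit_s + 1e-12)
    peak_window <- function(idx) {
      if (length(idx) == 0) {
        return(list(pos = NA_real_, neg = NA_real_,
                    pos_reason = NA_character_, neg_reason = NA_character_))
      }
      pos <- max(tr[idx]) - bmean
      neg <- min(tr[idx]) - bmean
      list(
        pos = if (pos > 0) pos else NA_real_,
        neg = if (neg < 0) neg else NA_real_,
        pos_reason = if (pos > 0) omission_reason(pos, rng, bsd) else NA_character_,
        neg_reason = if (neg < 0) omission_reason(neg, rng, bsd) else NA_character_
      )
    }
    pd <- peak_window(during)
    pa <- peak_window(after)
    auc_d <- if (length(during) >= 2) {
      trace_auc(tr[during], grid[during], baseline = bmean)
    } else list(auc_pos = NA_real_, auc_neg = NA_real_)
    auc_a <- if (length(after) >= 2) {
      trace_auc(tr[after], grid[after], baseline = bmean)
    } else list(auc_pos = NA_real_, auc_neg = NA_real_)
    li <- lat_idx[which.max(tr[lat_idx])]
    flat <- rng <= 0
    rows[[i]] <- tibble(
      trial = i,
      outcome = outcome,
      baseline_mean = bmean,
      baseline_sd = bsd,
      during_end_s = dur,
      peak_pos_during = pd$pos, peak_neg_during = pd$neg,
      peak_pos_after = pa$pos, peak_neg_after = pa$neg,
      omit_pos_during = flat | !is.na(pd$pos_reason),
      omit_neg_during = flat | !is.na(pd$neg_reason),
      omit_pos_after = flat | !is.na(pa$pos_reason),
      omit_neg_after = flat | !is.na(pa$neg_reason),
      reason_pos_during = if (flat) "zero range" else pd$pos_reason,
      reason_neg_during = if (flat) "zero range" else pd$neg_reason,
      reason_pos_after = if (flat) "zero range" else pa$pos_reason,
      reason_neg_after = if (flat) "zero range" else pa$neg_reason,
      latency_to_peak_s = grid[li],
      auc_pos_during = auc_d$auc_pos, auc_neg_during = auc_d$auc_neg,
      auc_pos_after = auc_a$auc_pos, auc_neg_after = auc_a$auc_neg
    )
  }
  out <- list_rbind(rows)
  keep <- intersect(c("subject", "condition", "trial_index"), names(meta))
  if (length(keep) > 0) out <- bind_cols(meta[, keep, drop = FALSE], out)
  out
}

#' Signed area under the curve of a trace segment
#'
#' Trapezoidal integrals of the positive and negative parts of the
#' baseline-subtracted trace; `auc_pos + auc_neg` equals the net integral.
#'
#' @param values dF/F samples.
#' @param time_s matching time stamps (uniform or not).
#' @param window optional `(t_start, t_end)` restricting the integral.
#' @param baseline baseline mean subtracted before splitting signs; default 0.
#' @return A list with `auc_pos` (>= 0) and `auc_neg` (<= 0), in dF/F x s.
#' @export
trace_auc <- function(values, time_s, window = NULL, baseline = 0) {
  if (!is.null(window)) {
    idx <- which(time_s >= window[1] - 1e-12 & time_s <= window[2] + 1e-12)
    if (length(idx) < 2) abort("AUC window contains fewer than two samples")
    values <- values[idx]
    time_s <- time_s[idx]
  }
  if (length(values) < 2) abort("AUC needs at least two samples")
  y <- values - baseline
  trapz <- function(z) sum(diff(time_s) * (z[-1] + z[-length(z)]) / 2)
  list(auc_pos = trapz(pmax(y, 0)), auc_neg = trapz(pmin(y, 0)))
}

#' Outcome-specific mean traces
#'
#' Averages aligned trials sample-wise within each behavioral outcome (the
#' within-subject average used before any across-animal averaging). Outcomes
#' with zero trials are absent from the result and are treated as undefined
#' downstream.
#'
#' @param aligned an `aligned_traces` object with outcome labels.
#' @return A tibble of class `outcome_means`: columns `outcome`, `time_s`,
#'   `mean_dff`, `n_trials`.
#' @export
outcome_mean_traces <- function(aligned) {
  outcomes <- as.character(aligned$trials$outcome)
  present <- unique(outcomes)
  present <- c(intersect(OUTCOME_LEVELS, present), setdiff(present, OUTCOME_LEVELS))
  rows <- map(present, function(o) {
    idx <- which(outcomes == o)
    tibble(
      outcome = o,
      time_s = aligned$time_s,
      mean_dff = colMeans(aligned$traces[idx, , drop = FALSE]),
      n_trials = length(idx)
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("outcome_means", class(out))
  attr(out, "sample_rate_hz") <- aligned$sample_rate_hz
  out
}

#' Escape-versus-failure trace distance
#'
#' The Euclidean norm of the difference between a subject's mean escape-trial
#' trace and mean failure-trial trace, computed sample-wise over the full
#' aligned window: `sqrt(sum((e_i - f_i)^2))`. The statistic is agnostic to
#' the amplitude and kinetics of either response and measures only how well
#' the signal separates the two outcomes. Returns `NA` (with a warning) when
#' either outcome mean is undefined.
#'
#' @param means an `outcome_means` tibble, or a plain data frame with columns
#'   `outcome`, `time_s`, `mean_dff`.
#' @param outcomes the pair of outcomes to compare; default escape vs failure.
#' @param window optional `(t_start, t_end)` restricting the comparison to
#'   part of the aligned grid (the full window is the default and the
#'   convention used throughout the package).
#' @return A single non-negative number (dF/F norm units), or `NA_real_`.
#' @export
trace_distance <- function(means, outcomes = c("escape", "failure"), window = NULL) {
  stopifnot(length(outcomes) == 2)
  a <- means[means$outcome == outcomes[1], , drop = FALSE]
  b <- means[means$outcome == outcomes[2], , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    warn(sprintf(
      "trace distance undefined: missing mean trace for %s",
      paste(outcomes[c(nrow(a) == 0, nrow(b) == 0)], collapse = " and ")
    ))
    return(NA_real_)
  }
  if (nrow(a) != nrow(b) || max(abs(a$time_s - b$time_s)) > 1e-9) {
    abort("outcome mean traces are on different time grids")
  }
  keep <- rep(TRUE, nrow(a))
  if (!is.null(window)) {
    keep <- a$time_s >= window[1] - 1e-12 & a$time_s <= window[2] + 1e-12
  }
  sqrt(sum((a$mean_dff[keep] - b$mean_dff[keep])^2))
}

#' Per-subject trace distances across conditions
#'
#' Convenience wrapper running [align_trials()], [outcome_mean_traces()] and
#' [trace_distance()] for every subject-condition recording of a synthetic
#' cohort (see [simulate_cohort()]).
#'
#' @param cohort an `lh_cohort` object.
#' @param window_s dF/F normalization window, seconds.
#' @param pre_s,post_s alignment window, seconds.
#' @return A tibble: `subject`, `condition`, `trace_distance`, `n_escape`,
#'   `n_failure`.
#' @export
cohort_trace_distances <- function(cohort, window_s = 100, pre_s = 5, post_s = 8) {
  cfg <- cohort$config
  rows <- list()
  for (sub in names(cohort$signals)) {
    for (cond in names(cohort$signals[[sub]])) {
      sig <- cohort$signals[[sub]][[cond]]
      dff <- compute_dff(sig, window_s = window_s)
      dff <- downsample_signal(dff, cfg$timelocked_rate_hz)
      tr <- cohort$trials[cohort$trials$subject == sub & cohort$trials$condition == cond, ]
      al <- align_trials(dff, tr, pre_s = pre_s, post_s = post_s)
      mm <- outcome_mean_traces(al)
      nE <- sum(tr$outcome == "escape")
      nF <- sum(tr$outcome == "failure")
      d <- if (nE > 0 && nF > 0) trace_distance(mm) else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        subject = sub, condition = cond, trace_distance = d,
        n_escape = nE, n_failure = nF
      )
    }
  }
  list_rbind(rows)
}
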