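# Shared fixtures and independent brute-force oracles. Oracles are written as
# plain loops, independent of the implementation paths they check.

test_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_subjects = 3, trials_per_session = 20,
      sample_rate_hz = 50, timelocked_rate_hz = 25,
      noise_sd = 0.01, drift_amplitude = 0.5, seed = 42
    ),
    list(...)
  )
  do.call(cohort_config, args)
}

# Well-mixed chain whose states are all visited often; used for estimator
# consistency checks so every row accumulates enough transitions.
balanced_matrix <- function() {
  matrix(c(
    0.5, 0.3, 0.2,
    0.2, 0.5, 0.3,
    0.3, 0.2, 0.5
  ), 3, 3, byrow = TRUE, dimnames = list(
    c("escape", "failure", "spontaneous"),
    c("escape", "failure", "spontaneous")
  ))
}

# Direct per-window evaluation of (s - median) / median.
oracle_dff <- function(x, rate, window_s = 100) {
  wlen <- round(window_s * rate)
  out <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- min(i + wlen - 1, length(x))
    m <- median(x[i:j])
    out[i:j] <- (x[i:j] - m) / m
    i <- j + 1
  }
  out
}

# Peak omission oracle: test both thresholds for a candidate amplitude.
oracle_omitted <- function(amplitude, trace, baseline_sd) {
  rng <- max(trace) - min(trace)
  if (rng <= 0) return(TRUE)
  abs(amplitude) < 0.05 * rng || abs(amplitude) < 3 * baseline_sd
}

# Brute-force interval scanner for motion bouts.
oracle_bouts <- function(speed, times, threshold, min_dur, frame_rate) {
  n <- length(speed)
  res <- list()
  i <- 1
  while (i <= n) {
    if (speed[i] > threshold) {
      j <- i
      while (j < n && speed[j + 1] > threshold) j <- j + 1
      if ((j - i + 1) / frame_rate >= min_dur - 1e-12) {
        res[[length(res) + 1]] <- c(times[i], times[j])
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(res) == 0) {
    matrix(numeric(0), ncol = 2)
  } else {
    do.call(rbind, res)
  }
}

# Run-length encoding oracle for one label.
oracle_runs <- function(seq, label) {
  lens <- integer(0)
  cur <- 0L
  for (s in c(seq, "_end_")) {
    if (identical(s, label)) {
      cur <- cur + 1L
    } else if (cur > 0) {
      lens <- c(lens, cur)
      cur <- 0L
    }
  }
  lens
}

# Pair-count transition probabilities from pooled sequences.
oracle_transitions <- function(seqs) {
  lv <- c("escape", "failure", "spontaneous")
  counts <- matrix(0, 3, 3, dimnames = list(lv, lv))
  for (s in seqs) {
    if (length(s) < 2) next
    for (k in 1:(length(s) - 1)) {
      counts[s[k], s[k + 1]] <- counts[s[k], s[k + 1]] + 1
    }
  }
  counts / ifelse(rowSums(counts) > 0, rowSums(counts), NA)
}
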