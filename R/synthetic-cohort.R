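# Synthetic cohort generator: shuttle-box trial sequences driven by
# condition-specific three-state transition matrices, outcome-specific dF/F
# transient templates embedded in a continuous raw fluorescence model, 2-D
# body-center tracks with scheduled motion bouts, and slow oscillatory ex vivo
# traces. Every output is a pure function of (config, seed) with ground truth
# attached, so every downstream stage can be tested by parameter recovery.

default_transition_matrices <- function() {
  m <- function(v) check_transition_matrix(matrix(v, 3, 3, byrow = TRUE))
  list(
    # rows: from escape / failure / spontaneous; cols: to escape / failure / spontaneous
    baseline = m(c(
      0.75, 0.20, 0.05,
      0.65, 0.30, 0.05,
      0.70, 0.25, 0.05
    )),
    LH = m(c(
      0.40, 0.55, 0.05,
      0.30, 0.65, 0.05,
      0.35, 0.60, 0.05
    )),
    `LH+KET` = m(c(
      0.62, 0.33, 0.05,
      0.55, 0.40, 0.05,
      0.60, 0.35, 0.05
    ))
  )
}

default_transient_params <- function() {
  # Raised-cosine lobes; amplitudes in dF/F, latencies in s from shock onset,
  # width = lobe half-width in s. Failures are biphasic (dip during the shock,
  # rebound after); escapes are monophasic rises; spontaneous crossings carry
  # no shock-locked transient. The learned-helplessness condition damps the
  # failure lobes and ketamine largely restores them; escape transients do not
  # change across conditions.
  tibble(
    outcome = c("escape", "escape", "escape", "failure", "failure", "failure",
                "spontaneous", "spontaneous", "spontaneous"),
    condition = rep(c("baseline", "LH", "LH+KET"), 3),
    neg_amplitude = c(0, 0, 0, -0.25, -0.06, -0.20, 0, 0, 0),
    pos_amplitude = c(0.40, 0.40, 0.40, 0.45, 0.15, 0.38, 0, 0, 0),
    neg_latency_s = c(NA, NA, NA, 1.5, 1.5, 1.5, NA, NA, NA),
    pos_latency_s = c(2.0, 2.0, 2.0, 4.5, 4.5, 4.5, NA, NA, NA),
    width_s = c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2)
  )
}

#' Configuration for a synthetic learned-helplessness cohort
#'
#' Bundles the shuttle-box protocol (trial counts, shock duration, inter-trial
#' intervals), the condition-specific behavioral transition matrices, the
#' outcome- and condition-specific transient templates, the raw-signal model
#' (baseline fluorescence, slow drift, noise), and the per-subject coupling
#' between baseline trace distance and later failure rates. Defaults emulate
#' the weak-induction paradigm: 100 escapable 3-s shocks per session with
#' random 5-15 s inter-shock intervals, photometry sampled at 1 kHz and
#' analyzed time-locked at 250 Hz, and condition failure rates near 25%
#' (baseline), 60% (LH), 35% (LH+KET).
#'
#' @param n_subjects number of animals.
#' @param conditions ordered condition labels.
#' @param transition_matrices named list (one per condition) of 3x3
#'   row-stochastic matrices over escape/failure/spontaneous.
#' @param trials_per_session shocks per session.
#' @param shock_duration_s shock length, seconds; failures are scored with
#'   latency equal to this cap.
#' @param iti_range_s min/max inter-shock interval, seconds.
#' @param sample_rate_hz raw photometry sampling rate, Hz.
#' @param timelocked_rate_hz analysis rate for event-aligned work, Hz; must
#'   divide `sample_rate_hz`.
#' @param pre_s,post_s peri-event window, seconds.
#' @param transient_params tibble of per (outcome, condition) template
#'   parameters, see [default_transient_params()] for the columns.
#' @param baseline_fluorescence raw fluorescence baseline level (a.u.).
#' @param noise_sd Gaussian noise SD in dF/F units.
#' @param drift_amplitude slow sinusoidal drift amplitude in raw units.
#' @param drift_period_s drift period, seconds.
#' @param subject_gain_range range of the per-subject gain multiplying the
#'   failure-template lobes (uniform draw); this is the source of individual
#'   variability in baseline trace distance.
#' @param coupling_slope change in failure fraction (0-1) per unit baseline
#'   trace distance, applied to the LH-condition failure probabilities around
#'   the cohort-expected distance. Negative values mean larger baseline
#'   separation predicts fewer failures (resilience).
#' @param seed master seed; per-subject substreams are derived from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12,
                          conditions = c("baseline", "LH", "LH+KET"),
                          transition_matrices = default_transition_matrices(),
                          trials_per_session = 100,
                          shock_duration_s = 3,
                          iti_range_s = c(5, 15),
                          sample_rate_hz = 1000,
                          timelocked_rate_hz = 250,
                          pre_s = 5,
                          post_s = 8,
                          transient_params = default_transient_params(),
                          baseline_fluorescence = 100,
                          noise_sd = 0.02,
                          drift_amplitude = 1,
                          drift_period_s = 600,
                          subject_gain_range = c(0.5, 1.5),
                          coupling_slope = -0.03,
                          seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, conditions = conditions,
    transition_matrices = transition_matrices,
    trials_per_session = trials_per_session,
    shock_duration_s = shock_duration_s, iti_range_s = iti_range_s,
    sample_rate_hz = sample_rate_hz, timelocked_rate_hz = timelocked_rate_hz,
    pre_s = pre_s, post_s = post_s,
    transient_params = as_tibble(transient_params),
    baseline_fluorescence = baseline_fluorescence,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_period_s = drift_period_s,
    subject_gain_range = subject_gain_range,
    coupling_slope = coupling_slope, seed = seed
  )
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config a candidate configuration list.
#' @export
validate_cohort_config <- function(config) {
  check_scalar_pos(config$n_subjects, "n_subjects")
  check_scalar_pos(config$trials_per_session, "trials_per_session")
  check_scalar_pos(config$shock_duration_s, "shock_duration_s")
  check_scalar_pos(config$sample_rate_hz, "sample_rate_hz")
  check_scalar_pos(config$timelocked_rate_hz, "timelocked_rate_hz")
  if (abs(config$sample_rate_hz / config$timelocked_rate_hz -
          round(config$sample_rate_hz / config$timelocked_rate_hz)) > 1e-9) {
    abort("`timelocked_rate_hz` must divide `sample_rate_hz`")
  }
  if (length(config$iti_range_s) != 2 || config$iti_range_s[1] <= 0 ||
      diff(config$iti_range_s) < 0) {
    abort("`iti_range_s` must be (min, max) with 0 < min <= max")
  }
  for (cond in config$conditions) {
    if (is.null(config$transition_matrices[[cond]])) {
      abort(sprintf("no transition matrix configured for condition `%s`", cond))
    }
    config$transition_matrices[[cond]] <-
      check_transition_matrix(config$transition_matrices[[cond]],
                              sprintf("transition_matrices$`%s`", cond))
  }
  tp <- config$transient_params
  need <- c("outcome", "condition", "neg_amplitude", "pos_amplitude",
            "neg_latency_s", "pos_latency_s", "width_s")
  if (!all(need %in% names(tp))) {
    abort(sprintf("transient_params must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(tp$width_s <= 0)) abort("transient widths must be > 0")
  if (!is.numeric(config$noise_sd) || config$noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(config, class = "cohort_config")
}

#' Simulate an outcome sequence from a transition matrix
#'
#' Samples a first-order three-state chain over escape/failure/spontaneous.
#'
#' @param transition_matrix 3x3 row-stochastic matrix (rows = from-state).
#' @param n_trials sequence length (>= 1).
#' @param initial_state the first trial's outcome; default `"escape"`.
#' @param seed integer seed; identical inputs give identical sequences.
#' @return A character vector of length `n_trials`.
#' @export
simulate_trial_sequence <- function(transition_matrix, n_trials,
                                    initial_state = "escape", seed = 1) {
  m <- check_transition_matrix(transition_matrix)
  check_scalar_pos(n_trials, "n_trials")
  initial_state <- check_outcomes(initial_state)
  out <- character(n_trials)
  out[1] <- initial_state
  if (n_trials > 1) {
    with_seed(seed, {
      u <- runif(n_trials - 1)
      for (i in 2:n_trials) {
        p <- cumsum(m[out[i - 1], ])
        out[i] <- OUTCOME_LEVELS[findInterval(u[i - 1], p, left.open = TRUE) + 1L]
      }
    })
  }
  out
}

# Raised-cosine lobe: amp at `latency`, smoothly falling to exactly zero at
# +/- width (compact support, so the two failure lobes never interact and the
# configured amplitude is the exact extremum). Analytic AUC = amp * width.
cosine_lobe <- function(time_grid, amp, latency, width) {
  u <- (time_grid - latency) / width
  ifelse(abs(u) < 1, amp * cos(pi * u / 2)^2, 0)
}

#' Outcome-specific dF/F transient template
#'
#' Builds the noiseless template on a relative time grid: failures are the sum
#' of a negative lobe inside the shock window and a positive rebound after
#' shock offset; escapes are a single positive lobe; spontaneous trials are
#' identically zero. Lobes are raised-cosine bumps with compact support, so
#' the configured amplitudes are the exact extrema at the configured
#' latencies and each lobe's area is `amplitude * width`.
#'
#' @param outcome `"escape"`, `"failure"` or `"spontaneous"`.
#' @param params one row of the `transient_params` table (list or one-row
#'   data frame).
#' @param time_grid relative time grid in seconds (0 = shock onset).
#' @return Numeric dF/F vector on `time_grid`.
#' @export
transient_template <- function(outcome, params, time_grid) {
  outcome <- check_outcomes(outcome)
  p <- as.list(params)
  tr <- numeric(length(time_grid))
  add_lobe <- function(amp, lat, width) {
    if (is.na(amp) || amp == 0) return(numeric(length(time_grid)))
    if (is.na(lat)) abort("lobe latency missing for a nonzero amplitude")
    if (lat < min(time_grid) || lat > max(time_grid)) {
      abort(sprintf("lobe latency %g s lies outside the time grid", lat))
    }
    cosine_lobe(time_grid, amp, lat, width)
  }
  if (outcome == "failure") {
    tr <- add_lobe(p$neg_amplitude, p$neg_latency_s, p$width_s) +
      add_lobe(p$pos_amplitude, p$pos_latency_s, p$width_s)
  } else if (outcome == "escape") {
    tr <- add_lobe(p$pos_amplitude, p$pos_latency_s, p$width_s)
  }
  tr
}

transient_row <- function(config, outcome, condition) {
  tp <- config$transient_params
  row <- tp[tp$outcome == outcome & tp$condition == condition, ]
  if (nrow(row) == 0) {
    abort(sprintf("no transient parameters for (%s, %s)", outcome, condition))
  }
  row[1, ]
}

# Subject-specific template: the per-subject gain scales the failure lobes
# (in all conditions), which is what makes baseline trace distance vary
# across animals.
subject_template <- function(config, outcome, condition, gain, time_grid) {
  row <- transient_row(config, outcome, condition)
  if (outcome == "failure") {
    row$neg_amplitude <- row$neg_amplitude * gain
    row$pos_amplitude <- row$pos_amplitude * gain
  }
  transient_template(outcome, row, time_grid)
}

analysis_grid <- function(config) {
  rate <- config$timelocked_rate_hz
  n_pre <- round(config$pre_s * rate)
  n_post <- round(config$post_s * rate)
  (seq_len(n_pre + n_post) - 1 - n_pre) / rate
}

# True escape-vs-failure trace distance for a subject gain, on the cohort's
# analysis grid: templates are laid down at the acquisition rate and
# block-mean decimated to the time-locked rate, exactly as the measurement
# pipeline does, so the noiseless pipeline recovers this value exactly.
true_trace_distance <- function(config, gain, condition = "baseline") {
  grid <- analysis_grid_full(config)
  e <- subject_template(config, "escape", condition, gain, grid)
  f <- subject_template(config, "failure", condition, gain, grid)
  k <- as.integer(round(config$sample_rate_hz / config$timelocked_rate_hz))
  if (k > 1) {
    grp <- (seq_along(e) - 1L) %/% k
    e <- as.numeric(tapply(e, grp, mean))
    f <- as.numeric(tapply(f, grp, mean))
  }
  sqrt(sum((e - f)^2))
}

# Expected distance at the mean gain: the coupling reference point. Depends
# only on the config, so adding subjects never moves it.
reference_distance <- function(config) {
  true_trace_distance(config, mean(config$subject_gain_range))
}

# Shift the failure share of each row by `delta` in *non-spontaneous fraction*
# units (the scale on which failure percentages are scored downstream), with
# escape absorbing the complement; clipped away from the simplex edges.
shift_failure_prob <- function(m, delta, eps = 0.02) {
  out <- m
  for (r in 1:3) {
    ps <- m[r, "spontaneous"]
    pf <- min(max(m[r, "failure"] + delta * (1 - ps), eps), 1 - ps - eps)
    out[r, "failure"] <- pf
    out[r, "escape"] <- 1 - ps - pf
  }
  out
}

#' Simulate one subject's behavior, photometry and ground truth
#'
#' Generates, for each condition, a trial table (outcomes from the subject's
#' transition chain, onsets spaced by shock duration plus random inter-trial
#' intervals, escape latencies uniform on (0.3 s, shock duration), failures at
#' the cap) and a continuous raw fluorescence recording:
#' `B * (1 + sum of trial templates + dF/F noise) + drift`, with baseline
#' level `B`, slow sinusoidal drift and Gaussian noise. With zero noise and
#' zero drift the windowed-median dF/F recovers the embedded templates
#' exactly, which is what makes the preprocessing testable by inversion.
#'
#' @param config a `cohort_config`.
#' @param subject_index subject number (1-based).
#' @return A list with `trials` (tibble across conditions), `signals` (named
#'   list of raw `photometry_signal`, one per condition), and `truth` (gain,
#'   true baseline trace distance, per-condition transition matrices and
#'   expected failure probability).
#' @export
simulate_subject <- function(config, subject_index) {
  config <- validate_cohort_config(config)
  sid <- sprintf("s%02d", subject_index)
  gain <- with_seed(subject_seed(config$seed, subject_index, salt = 1L),
                    runif(1, config$subject_gain_range[1], config$subject_gain_range[2]))
  d_true <- true_trace_distance(config, gain)
  d_ref <- reference_distance(config)

  rate <- config$sample_rate_hz
  dur <- config$shock_duration_s
  pad <- config$pre_s + 2
  trials_all <- list()
  signals <- list()
  matrices <- list()
  p_fail <- numeric(0)

  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    m <- config$transition_matrices[[cond]]
    if (cond == "LH" && config$coupling_slope != 0) {
      target <- stationary_failure_prob(m) +
        config$coupling_slope * (d_true - d_ref)
      m <- solve_failure_shift(m, min(max(target, 0.05), 0.95))
    }
    matrices[[cond]] <- m
    outcomes <- simulate_trial_sequence(
      m, config$trials_per_session,
      initial_state = "escape",
      seed = subject_seed(config$seed, subject_index, salt = 10L + ci)
    )
    n <- length(outcomes)
    sim <- with_seed(subject_seed(config$seed, subject_index, salt = 100L + ci), {
      itis <- runif(n, config$iti_range_s[1], config$iti_range_s[2])
      lat <- runif(n, 0.3, dur)
      list(itis = itis, lat = lat)
    })
    onsets <- pad + cumsum(c(0, (dur + sim$itis)[-n]))
    # quantize onsets to the time-locked analysis grid so decimated aligned
    # windows sit in phase with the embedded templates
    onsets <- round(onsets * config$timelocked_rate_hz) / config$timelocked_rate_hz
    latency <- ifelse(outcomes == "escape", sim$lat,
                      ifelse(outcomes == "failure", dur, NA_real_))
    total_s <- onsets[n] + dur + config$post_s + 2
    nsamp <- ceiling(total_s * rate)
    tgrid <- (seq_len(nsamp) - 1) / rate

    dff_clean <- numeric(nsamp)
    for (k in seq_len(n)) {
      if (outcomes[k] == "spontaneous") next
      i0 <- round(onsets[k] * rate)
      rel <- analysis_grid_full(config)
      tmpl <- subject_template(config, outcomes[k], cond, gain, rel)
      idx <- i0 + seq_along(rel) - round(config$pre_s * rate)
      okk <- idx >= 1 & idx <= nsamp
      dff_clean[idx[okk]] <- dff_clean[idx[okk]] + tmpl[okk]
    }
    B <- config$baseline_fluorescence
    noise <- if (config$noise_sd > 0) {
      with_seed(subject_seed(config$seed, subject_index, salt = 1000L + ci),
                rnorm(nsamp, 0, config$noise_sd))
    } else numeric(nsamp)
    drift <- if (config$drift_amplitude > 0) {
      config$drift_amplitude * sin(2 * pi * tgrid / config$drift_period_s)
    } else numeric(nsamp)
    raw <- B * (1 + dff_clean + noise) + drift

    signals[[cond]] <- photometry_signal(raw, rate, kind = "raw")
    trials_all[[cond]] <- tibble(
      subject = sid, condition = cond, trial_index = seq_len(n),
      onset_s = onsets, shock_duration_s = dur,
      outcome = outcomes, latency_s = latency
    )
    p_fail[cond] <- stationary_failure_prob(m)
  }

  list(
    trials = list_rbind(trials_all),
    signals = signals,
    truth = list(
      subject = sid, gain = gain, true_distance = d_true,
      reference_distance = d_ref,
      transition_matrices = matrices,
      expected_failure_prob = p_fail
    )
  )
}

# Template support grid at the *raw* sampling rate for embedding.
analysis_grid_full <- function(config) {
  rate <- config$sample_rate_hz
  n_pre <- round(config$pre_s * rate)
  n_post <- round(config$post_s * rate)
  (seq_len(n_pre + n_post) - 1 - n_pre) / rate
}

# Row shift whose chain has exactly the target stationary failure fraction:
# the stationary fraction is monotone in the shift, so a scalar root-find
# makes the designed per-subject coupling hold on the fraction scale itself.
solve_failure_shift <- function(m, target_frac) {
  g <- function(delta) stationary_failure_prob(shift_failure_prob(m, delta)) - target_frac
  delta <- stats::uniroot(g, c(-0.995, 0.995), tol = 1e-12)$root
  shift_failure_prob(m, delta)
}

# Stationary failure fraction among non-spontaneous trials (power iteration);
# this is the quantity failure percentages estimate downstream.
stationary_failure_prob <- function(m) {
  v <- rep(1 / 3, 3)
  for (i in 1:200) v <- as.numeric(v %*% m)
  v[2] / (v[1] + v[2])
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_subject()] for every animal. Subjects use independent
#' derived random substreams, so adding a subject never changes the others.
#'
#' @param config a `cohort_config`.
#' @return An object of class `lh_cohort`: `config`, `trials` (all subjects),
#'   `signals` (nested list subject -> condition), `truth` (tibble with
#'   list-columns).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  subs <- map(seq_len(config$n_subjects), function(i) simulate_subject(config, i))
  truth <- list_rbind(map(subs, function(s) {
    tibble(
      subject = s$truth$subject, gain = s$truth$gain,
      true_distance = s$truth$true_distance,
      expected_failure_prob = list(s$truth$expected_failure_prob),
      transition_matrices = list(s$truth$transition_matrices)
    )
  }))
  signals <- setNames(map(subs, function(s) s$signals),
                      map_chr(subs, function(s) s$truth$subject))
  structure(
    list(
      config = config,
      trials = list_rbind(map(subs, function(s) s$trials)),
      signals = signals,
      truth = truth
    ),
    class = "lh_cohort"
  )
}

#' @export
print.lh_cohort <- function(x, ...) {
  cat(sprintf(
    "<lh_cohort: %d subjects x %d conditions, %d trials/session, %g Hz>\n",
    x$config$n_subjects, length(x$config$conditions),
    x$config$trials_per_session, x$config$sample_rate_hz
  ))
  invisible(x)
}

#' Simulate a 2-D body-center track with scheduled motion bouts
#'
#' The animal is stationary except during scheduled bouts, when it moves in a
#' straight line at the scheduled speed; optional Gaussian position jitter is
#' added on top. Bouts must be non-overlapping and inside the recording.
#'
#' @param duration_s recording length, seconds.
#' @param frame_rate frames per second; default 30.
#' @param bout_schedule tibble with `onset_s`, `offset_s`, `speed_mm_s` (may
#'   have zero rows).
#' @param noise_sd position jitter SD in mm; default 0.
#' @param seed integer seed.
#' @return A tibble of class `track`: `time_s`, `x_mm`, `y_mm`, with the
#'   schedule kept in the `true_bouts` attribute.
#' @export
simulate_track <- function(duration_s, frame_rate = 30,
                           bout_schedule = tibble(onset_s = numeric(),
                                                  offset_s = numeric(),
                                                  speed_mm_s = numeric()),
                           noise_sd = 0, seed = 1) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(frame_rate, "frame_rate")
  bs <- as_tibble(bout_schedule)
  if (nrow(bs) > 0) {
    bs <- arrange(bs, .data$onset_s)
    if (any(bs$onset_s < 0) || any(bs$offset_s > duration_s) ||
        any(bs$offset_s <= bs$onset_s)) {
      abort("bout schedule must satisfy 0 <= onset < offset <= duration")
    }
    if (nrow(bs) > 1 && any(bs$onset_s[-1] < bs$offset_s[-nrow(bs)])) {
      abort("bout schedule contains overlapping bouts")
    }
  }
  n <- floor(duration_s * frame_rate) + 1
  t <- (seq_len(n) - 1) / frame_rate
  v <- numeric(n)
  for (k in seq_len(nrow(bs))) {
    v[t >= bs$onset_s[k] & t < bs$offset_s[k]] <- bs$speed_mm_s[k]
  }
  # integrate speed along +x
  x <- cumsum(c(0, v[-n] / frame_rate))
  y <- numeric(n)
  if (noise_sd > 0) {
    with_seed(seed, {
      x <- x + rnorm(n, 0, noise_sd)
      y <- y + rnorm(n, 0, noise_sd)
    })
  }
  out <- tibble(time_s = t, x_mm = x, y_mm = y)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "true_bouts") <- bs
  class(out) <- c("track", class(out))
  out
}

#' Simulate a slow oscillatory calcium trace
#'
#' A sinusoid of the given frequency plus Gaussian noise, emulating the ~1 Hz
#' spontaneous oscillations seen in ex vivo dopamine-neuron calcium imaging.
#'
#' @param freq_hz oscillation frequency (must be below Nyquist); 0 gives a
#'   constant trace.
#' @param duration_s trace length, seconds.
#' @param sample_rate_hz sampling rate; default 12.
#' @param amplitude sinusoid amplitude; default 1.
#' @param noise_sd additive Gaussian noise SD; default 0.
#' @param seed integer seed.
#' @return A `photometry_signal` (kind `"dff"`).
#' @export
simulate_oscillation <- function(freq_hz, duration_s, sample_rate_hz = 12,
                                 amplitude = 1, noise_sd = 0, seed = 1) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(sample_rate_hz, "sample_rate_hz")
  if (freq_hz < 0 || freq_hz >= sample_rate_hz / 2) {
    abort("`freq_hz` must lie in [0, sample_rate_hz / 2)")
  }
  n <- floor(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- amplitude * sin(2 * pi * freq_hz * t)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  photometry_signal(x, sample_rate_hz, kind = "dff")
}

#' Write cohort tables to disk
#'
#' Writes the trial table as CSV, ground truth as JSON, and the configuration
#' as YAML into `dir`; per-subject photometry goes to one CSV per
#' subject-condition recording (`time_s`, `value`).
#'
#' @param cohort an `lh_cohort`.
#' @param dir output directory (created if needed).
#' @param write_signals write the (large) photometry CSVs too? default TRUE.
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, dir, write_signals = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "trials.csv")
  readr::write_csv(cohort$trials, f)
  files <- c(files, f)
  truth <- cohort$truth
  truth_json <- map(seq_len(nrow(truth)), function(i) {
    list(
      subject = truth$subject[i], gain = truth$gain[i],
      true_distance = truth$true_distance[i],
      expected_failure_prob = as.list(truth$expected_failure_prob[[i]]),
      transition_matrices = map(truth$transition_matrices[[i]], function(m) {
        unname(apply(m, 1, as.list))
      })
    )
  })
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth_json, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(dir, "config.yaml")
  yaml::write_yaml(cohort_config_to_list(cohort$config), f)
  files <- c(files, f)
  if (write_signals) {
    for (sub in names(cohort$signals)) {
      for (cond in names(cohort$signals[[sub]])) {
        f <- file.path(dir, sprintf("photometry_%s_%s.csv", sub, gsub("[^A-Za-z0-9]", "", cond)))
        readr::write_csv(as_tibble(cohort$signals[[sub]][[cond]]), f)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}

# Plain-list view of a config for YAML round-tripping.
cohort_config_to_list <- function(config) {
  out <- unclass(config)
  out$transition_matrices <- map(out$transition_matrices, function(m) {
    lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))
  })
  out$transient_params <- as.list(as.data.frame(out$transient_params))
  out
}

#' @rdname write_cohort
#' @param lst a plain list as produced by YAML parsing.
#' @export
cohort_config_from_list <- function(lst) {
  lst$transition_matrices <- map(lst$transition_matrices, function(rows) {
    check_transition_matrix(do.call(rbind, lapply(rows, as.numeric)))
  })
  lst$transient_params <- as_tibble(lst$transient_params)
  do.call(cohort_config, lst)
}
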