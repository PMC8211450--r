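# Pipeline configuration and the end-to-end runner: generate a synthetic
# cohort, preprocess photometry, quantify transients and trace distances,
# summarize behavior, run locomotion and spectral demonstrations, correlate
# cohort statistics, and write every artifact with a checksummed manifest.

run_config_defaults <- function() {
  list(
    window_s = 100,          # dF/F normalization window
    sample_rate_hz = 1000,   # raw acquisition rate
    timelocked_rate_hz = 250, # event-aligned analysis rate
    slow_rate_hz = 10,       # non-time-locked analysis rate
    pre_s = 5,
    post_s = 8,
    speed_threshold_mm_s = 30,
    min_bout_duration_s = 0.5,
    failure_bin_width = 4,
    welch_segment_length = 256,
    welch_overlap = 0.5,
    n_subjects = 6,
    trials_per_session = 30,
    seed = 1,
    verbose = TRUE
  )
}

#' Validate a pipeline run configuration
#'
#' Fills defaults, rejects unknown keys, and reports every violated
#' constraint with the offending field name. An empty input returns the full
#' defaults.
#'
#' @param config a named list of overrides, a YAML string, or a YAML file
#'   path; `NULL` gives defaults.
#' @return A validated list of class `run_config`.
#' @export
validate_run_config <- function(config = NULL) {
  defaults <- run_config_defaults()
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort("run config must be a named list or YAML document")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown run config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  errors <- character(0)
  for (f in c("window_s", "sample_rate_hz", "timelocked_rate_hz", "slow_rate_hz",
              "pre_s", "post_s", "speed_threshold_mm_s", "min_bout_duration_s",
              "failure_bin_width", "welch_segment_length", "n_subjects",
              "trials_per_session")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      errors <- c(errors, sprintf("`%s` must be a single positive number", f))
    }
  }
  if (is.numeric(cfg$welch_overlap) &&
      (cfg$welch_overlap < 0 || cfg$welch_overlap >= 1)) {
    errors <- c(errors, "`welch_overlap` must be in [0, 1)")
  }
  if (is.numeric(cfg$sample_rate_hz) && is.numeric(cfg$timelocked_rate_hz) &&
      cfg$timelocked_rate_hz > 0 &&
      abs(cfg$sample_rate_hz / cfg$timelocked_rate_hz -
          round(cfg$sample_rate_hz / cfg$timelocked_rate_hz)) > 1e-9) {
    errors <- c(errors, "`timelocked_rate_hz` must divide `sample_rate_hz`")
  }
  if (length(errors) > 0) abort(paste(errors, collapse = "\n"))
  structure(cfg, class = "run_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort, runs dF/F normalization, downsampling, trial alignment,
#' transient metrics, per-subject trace distances, behavioral summaries
#' (failure statistics, learning curves, transition models and similarities,
#' run lengths, Gaussian failure fit), a locomotion bout demonstration, a
#' Welch PSD demonstration, and cohort correlations, writing each report as
#' CSV/JSON under `out_dir` and finishing with a `manifest.json` listing every
#' artifact with its MD5 checksum. Identical configs and seeds produce
#' byte-identical artifacts and manifests.
#'
#' @param config a `run_config` (see [validate_run_config()]) or overrides.
#' @param out_dir output directory.
#' @param seed overrides the config seed if given.
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- isTRUE(cfg$verbose)
  artifacts <- character(0)
  emit_csv <- function(x, name) {
    f <- file.path(out_dir, name)
    readr::write_csv(x, f)
    artifacts <<- c(artifacts, f)
  }
  emit_json <- function(x, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, f)
  }

  pipeline_log(v, "generate: %d subjects, %d trials/session, %g Hz",
               cfg$n_subjects, cfg$trials_per_session, cfg$sample_rate_hz)
  ccfg <- cohort_config(
    n_subjects = cfg$n_subjects,
    trials_per_session = cfg$trials_per_session,
    sample_rate_hz = cfg$sample_rate_hz,
    timelocked_rate_hz = cfg$timelocked_rate_hz,
    pre_s = cfg$pre_s, post_s = cfg$post_s,
    seed = cfg$seed
  )
  cohort <- simulate_cohort(ccfg)
  emit_csv(cohort$trials, "trials.csv")
  yaml::write_yaml(cohort_config_to_list(ccfg), file.path(out_dir, "cohort_config.yaml"))
  artifacts <- c(artifacts, file.path(out_dir, "cohort_config.yaml"))

  pipeline_log(v, "preprocess + transients")
  metrics_all <- list()
  distances <- cohort_trace_distances(cohort, window_s = cfg$window_s,
                                      pre_s = cfg$pre_s, post_s = cfg$post_s)
  n_excluded <- 0L
  for (sub in names(cohort$signals)) {
    for (cond in names(cohort$signals[[sub]])) {
      dff <- compute_dff(cohort$signals[[sub]][[cond]], window_s = cfg$window_s)
      dff <- downsample_signal(dff, cfg$timelocked_rate_hz)
      tr <- cohort$trials[cohort$trials$subject == sub & cohort$trials$condition == cond, ]
      al <- suppressWarnings(align_trials(dff, tr, pre_s = cfg$pre_s, post_s = cfg$post_s))
      n_excluded <- n_excluded + nrow(al$excluded)
      metrics_all[[paste(sub, cond)]] <- transient_metrics(al, post_limit_s = cfg$post_s)
    }
  }
  if (n_excluded > 0) pipeline_log(v, "excluded %d trial(s) during alignment", n_excluded)
  emit_csv(list_rbind(metrics_all), "transient_metrics.csv")
  emit_csv(distances, "trace_distances.csv")

  pipeline_log(v, "behavior")
  fs <- failure_stats(group_by(cohort$trials, .data$subject, .data$condition))
  emit_csv(fs, "failure_stats.csv")
  curves <- cohort$trials |>
    group_by(.data$subject, .data$condition) |>
    group_modify(~ learning_curve(.x$outcome)) |>
    ungroup()
  emit_csv(curves, "learning_curves.csv")
  models <- map(
    setNames(ccfg$conditions, ccfg$conditions),
    function(cond) transition_model(cohort$trials[cohort$trials$condition == cond, ])
  )
  emit_csv(list_rbind(imap(models, function(m, cond) {
    mutate(generics::tidy(m), condition = cond, .before = 1)
  })), "transition_models.csv")
  safe_sim <- function(a, b) {
    tryCatch(model_similarity(a, b), error = function(e) NA_real_)
  }
  sims <- tibble(
    pair = c("baseline_vs_LH", "baseline_vs_LH+KET", "LH_vs_LH+KET"),
    similarity = c(
      safe_sim(models$baseline, models$LH),
      safe_sim(models$baseline, models$`LH+KET`),
      safe_sim(models$LH, models$`LH+KET`)
    )
  )
  emit_csv(sims, "model_similarity.csv")
  runs <- cohort$trials |>
    group_by(.data$subject, .data$condition) |>
    group_modify(~ run_length_stats(.x$outcome)) |>
    ungroup()
  emit_csv(runs, "run_length_stats.csv")
  lh_pct <- fs$pct_failures[fs$condition == "LH"]
  if (sum(is.finite(lh_pct)) >= 3) {
    fit <- fit_failure_distribution(lh_pct, bin_width = cfg$failure_bin_width)
    emit_json(list(mu = fit$mu, sigma = fit$sigma, n = fit$n,
                   bin_width = fit$bin_width), "failure_distribution_fit.json")
  }

  pipeline_log(v, "locomotion demo")
  trk <- simulate_track(
    duration_s = 180, frame_rate = 30,
    bout_schedule = tibble(
      onset_s = c(20, 60, 110), offset_s = c(26, 63, 118),
      speed_mm_s = c(60, 45, 80)
    ),
    noise_sd = 0.2, seed = cfg$seed
  )
  bouts <- detect_bouts(track_speed(trk),
                        threshold_mm_s = cfg$speed_threshold_mm_s,
                        min_duration_s = cfg$min_bout_duration_s)
  emit_csv(as_tibble(bouts), "motion_bouts.csv")
  emit_csv(distance_per_minute(trk), "distance_per_minute.csv")

  pipeline_log(v, "spectral demo")
  osc <- simulate_oscillation(1, 300, 12, noise_sd = 0.3, seed = cfg$seed)
  psd <- welch_psd(osc, segment_length = cfg$welch_segment_length,
                   overlap = cfg$welch_overlap)
  emit_csv(as_tibble(psd), "psd.csv")
  emit_json(list(max_power = max_power(psd),
                 freq_at_max_power_hz = freq_at_max_power(psd)), "psd_summary.json")

  pipeline_log(v, "correlate")
  base_d <- distances[distances$condition == "baseline", c("subject", "trace_distance")]
  lh_f <- fs[fs$condition == "LH", c("subject", "pct_failures")]
  joined <- inner_join(base_d, lh_f, by = "subject")
  joined <- joined[is.finite(joined$trace_distance) & is.finite(joined$pct_failures), ]
  if (nrow(joined) >= 3) {
    cc <- correlate_pearson(joined$trace_distance, joined$pct_failures)
    emit_csv(joined, "distance_vs_failures.csv")
    emit_json(as.list(cc), "correlation.json")
  }

  manifest <- tibble(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  ) |> arrange(.data$file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(v, "done: %d artifacts", nrow(manifest))
  invisible(manifest)
}
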