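# build a minimal aligned_traces object directly from a matrix
make_aligned <- function(traces, rate = 250, pre_s = 5, post_s = 8,
                         outcome = "failure", shock_duration_s = 3,
                         latency_s = NA_real_) {
  n <- nrow(traces)
  structure(
    list(
      traces = traces,
      time_s = (seq_len(ncol(traces)) - 1 - pre_s * rate) / rate,
      trials = tibble::tibble(
        outcome = rep_len(outcome, n),
        shock_duration_s = rep_len(shock_duration_s, n),
        latency_s = rep_len(latency_s, n)
      ),
      sample_rate_hz = rate, pre_s = pre_s, post_s = post_s,
      excluded = tibble::tibble()
    ),
    class = "aligned_traces"
  )
}

grid_250 <- function() (0:(13 * 250 - 1)) / 250 - 5

test_that("baseline statistics cover exactly the 5 s pre-onset segment", {
  z <- make_aligned(matrix(0, 1, 13 * 250))
  b <- baseline_stats(z)
  expect_equal(b$baseline_mean, 0)
  expect_equal(b$baseline_sd, 0)

  # repeated [1,1,1,3] pattern in the pre-window: direct formula oracle
  g <- grid_250()
  pre <- g < 0
  tr <- numeric(length(g))
  tr[pre] <- rep_len(c(1, 1, 1, 3), sum(pre))
  b <- baseline_stats(make_aligned(matrix(tr, 1)))
  expect_equal(b$baseline_mean, mean(rep_len(c(1, 1, 1, 3), sum(pre))))
  expect_equal(b$baseline_sd, sd(rep_len(c(1, 1, 1, 3), sum(pre))))

  # linear ramp 0 -> 1 over the pre-window: mean 1/2 up to grid resolution
  tr2 <- numeric(length(g))
  tr2[pre] <- seq(0, 1, length.out = sum(pre))
  b2 <- baseline_stats(make_aligned(matrix(tr2, 1)))
  expect_equal(b2$baseline_mean, 0.5, tolerance = 1e-3)

  short <- make_aligned(matrix(0, 1, 10 * 250), pre_s = 2)
  expect_error(baseline_stats(short), "baseline segment")
})

test_that("peaks, windows, latency and omission follow the during/after rules", {
  g <- grid_250()
  p <- list(neg_amplitude = -0.2, pos_amplitude = 0.5,
            neg_latency_s = 1.5, pos_latency_s = 4.0, width_s = 1.2)
  tr <- transient_template("failure", p, g)
  al <- make_aligned(matrix(tr, 1), shock_duration_s = 3)
  m <- transient_metrics(al)
  expect_equal(m$peak_neg_during, -0.2, tolerance = 1e-9)
  expect_equal(m$peak_pos_after, 0.5, tolerance = 1e-9)
  expect_equal(m$latency_to_peak_s, 4.0, tolerance = 1e-9)
  expect_false(m$omit_neg_during)
  expect_false(m$omit_pos_after)

  # a 0.01 bump on a trace with range 1.0 is omitted by the 5%-of-range rule
  tr2 <- numeric(length(g))
  tr2[g >= 4 & g <= 5] <- 1.0    # dominant after-shock peak sets the range
  tr2[g >= 0.5 & g <= 1] <- 0.01 # tiny during-shock bump
  al2 <- make_aligned(matrix(tr2, 1))
  m2 <- transient_metrics(al2)
  expect_equal(m2$peak_pos_during, 0.01)
  expect_true(m2$omit_pos_during)
  expect_match(m2$reason_pos_during, "below 5% of range")
  expect_false(m2$omit_pos_after)

  # flat trace: everything omitted with reason "zero range"
  alf <- make_aligned(matrix(1, 1, 13 * 250))
  mf <- transient_metrics(alf)
  expect_true(all(is.na(c(mf$peak_pos_during, mf$peak_neg_during))))
  expect_true(all(c(mf$omit_pos_during, mf$omit_neg_during,
                    mf$omit_pos_after, mf$omit_neg_after)))
  expect_equal(mf$reason_pos_during, "zero range")

  # escape trials: the during-window ends at the recorded escape time
  esc <- numeric(length(g))
  esc[g >= 0 & g <= 0.9] <- 0.3 # bump before the 1 s escape
  esc[g >= 2 & g <= 2.5] <- 0.6 # bump after escape but before shock end
  ale <- make_aligned(matrix(esc, 1), outcome = "escape",
                      shock_duration_s = 3, latency_s = 1)
  me <- transient_metrics(ale)
  expect_equal(me$during_end_s, 1)
  expect_equal(me$peak_pos_during, 0.3)
  expect_equal(me$peak_pos_after, 0.6)
})

test_that("omission decisions match a brute-force oracle on 200 random traces", {
  set.seed(101)
  g <- grid_250()
  pre <- g < 0
  for (rep in 1:200) {
    tr <- cumsum(rnorm(length(g), 0, 0.01))       # random-walk trace
    tr <- tr + rnorm(length(g), 0, runif(1, 0, 0.05))
    al <- make_aligned(matrix(tr, 1), shock_duration_s = 3)
    m <- transient_metrics(al)
    bmean <- mean(tr[pre])
    bsd <- sd(tr[pre])
    during <- tr[g >= 0 & g <= 3]
    after <- tr[g > 3 & g <= 8]
    amps <- c(pos_during = max(during) - bmean, neg_during = min(during) - bmean,
              pos_after = max(after) - bmean, neg_after = min(after) - bmean)
    flags <- c(m$omit_pos_during, m$omit_neg_during, m$omit_pos_after, m$omit_neg_after)
    signs <- c(1, -1, 1, -1)
    for (j in 1:4) {
      if (sign(amps[j]) == signs[j]) { # peak reported: compare decisions
        expect_identical(unname(flags[j]), oracle_omitted(amps[j], tr, bsd))
      }
    }
    # latency oracle: earliest argmax within [0, 8]
    win <- which(g >= 0 & g <= 8)
    expect_equal(m$latency_to_peak_s, g[win[which.max(tr[win])]])
  }
})

test_that("latency tie-break picks the earliest sample and survives duplication", {
  g <- grid_250()
  tr <- numeric(length(g))
  tr[abs(g - 2) < 1e-9] <- 1
  tr[abs(g - 6) < 1e-9] <- 1 # tie at 2 s and 6 s
  m1 <- transient_metrics(make_aligned(matrix(tr, 1)))
  expect_equal(m1$latency_to_peak_s, 2)
  m2 <- transient_metrics(make_aligned(matrix(rep(tr, each = 2), 2, byrow = FALSE)))
  expect_equal(unique(m2$latency_to_peak_s), 2)
})

test_that("trapezoidal AUC matches closed forms and decomposes by sign", {
  # half-sine lobe, amplitude 0.5, duration 2 s: integral = 2 A d / pi
  rate <- 250
  t <- seq(0, 2, by = 1 / rate)
  y <- 0.5 * sin(pi * t / 2)
  a <- trace_auc(y, t)
  expect_equal(a$auc_pos, 2 * 0.5 * 2 / pi, tolerance = 0.01)
  expect_equal(a$auc_neg, 0)

  z <- trace_auc(numeric(100), seq(0, 1, length.out = 100))
  expect_equal(z$auc_pos, 0)
  expect_equal(z$auc_neg, 0)

  # mirror-symmetric lobes cancel: auc_pos = -auc_neg, net integral 0
  t2 <- seq(0, 4, by = 1 / rate)
  y2 <- sin(pi * t2 / 2) * 0.3
  a2 <- trace_auc(y2, t2)
  expect_equal(a2$auc_pos, -a2$auc_neg, tolerance = 1e-9)

  expect_error(trace_auc(y2, t2, window = c(10, 11)), "fewer than two samples")
})

test_that("outcome means average sample-wise and converge to the template", {
  g <- grid_250()
  row <- sin(g)
  al <- make_aligned(rbind(row, row), outcome = "escape")
  mm <- outcome_mean_traces(al)
  expect_equal(mm$mean_dff, row, ignore_attr = TRUE)

  al2 <- make_aligned(rbind(c(0, 1), c(2, 3)), rate = 1, pre_s = 1, post_s = 1,
                      outcome = c("escape", "escape"))
  mm2 <- outcome_mean_traces(al2)
  expect_equal(mm2$mean_dff, c(1, 2))

  # CLT: 500 noisy copies of a template are within 3 sd/sqrt(500) of it
  set.seed(7)
  noise_sd <- 0.05
  tmpl <- 0.3 * exp(-((g - 2)^2))
  noisy <- matrix(rep(tmpl, each = 500), 500) +
    matrix(rnorm(500 * length(g), 0, noise_sd), 500)
  mm3 <- outcome_mean_traces(make_aligned(noisy, outcome = "failure"))
  expect_lt(max(abs(mm3$mean_dff - tmpl)), 5 * noise_sd / sqrt(500))
})

test_that("trace distance is the Euclidean norm with metric properties", {
  mk <- function(e, f) {
    tibble::tibble(
      outcome = rep(c("escape", "failure"), each = length(e)),
      time_s = rep(seq_along(e), 2),
      mean_dff = c(e, f)
    )
  }
  expect_equal(trace_distance(mk(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(trace_distance(mk(c(1, 1), c(0, 0))), sqrt(2))
  # translation invariance
  e <- rnorm(50); f <- rnorm(50)
  expect_equal(trace_distance(mk(e + 5, f + 5)), trace_distance(mk(e, f)))
  # symmetry and triangle inequality on random triples
  set.seed(21)
  for (k in 1:25) {
    a <- rnorm(30); b <- rnorm(30); c <- rnorm(30)
    dab <- trace_distance(mk(a, b))
    dba <- trace_distance(mk(b, a))
    dac <- trace_distance(mk(a, c))
    dcb <- trace_distance(mk(c, b))
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  # missing outcome mean -> flagged missing
  half <- tibble::tibble(outcome = "escape", time_s = 1:3, mean_dff = c(1, 2, 3))
  expect_warning(d <- trace_distance(half), "undefined")
  expect_true(is.na(d))
})

test_that("learned helplessness damps trace distance and ketamine restores it", {
  cfg <- test_config(n_subjects = 2, trials_per_session = 30)
  coh <- simulate_cohort(cfg)
  d <- cohort_trace_distances(coh)
  wide <- tidyr::pivot_wider(d[, c("subject", "condition", "trace_distance")],
                             names_from = "condition", values_from = "trace_distance")
  expect_true(all(wide$LH < wide$baseline, na.rm = TRUE))
  expect_true(all(wide$`LH+KET` > wide$LH, na.rm = TRUE))
})
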