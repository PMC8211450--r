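test_that("failure percentage and mean latency follow the scoring rules", {
  tr <- tibble::tibble(
    outcome = c(rep("failure", 12), rep("escape", 18)),
    latency_s = c(rep(10, 12), runif(18, 0.3, 9))
  )
  fs <- failure_stats(tr)
  expect_equal(fs$pct_failures, 40)

  # all failures under the strong-paradigm 10 s cap
  allf <- tibble::tibble(outcome = rep("failure", 8), latency_s = 10)
  expect_equal(failure_stats(allf)$mean_latency_s, 10)

  # escapes at 2 s and 4 s plus one capped failure: mean 16/3
  mix <- tibble::tibble(outcome = c("escape", "escape", "failure"),
                        latency_s = c(2, 4, 10))
  expect_equal(failure_stats(mix)$mean_latency_s, 16 / 3)

  # spontaneous-only input is flagged missing
  sp <- tibble::tibble(outcome = rep("spontaneous", 4), latency_s = NA_real_)
  expect_true(is.na(failure_stats(sp)$pct_failures))

  # grouping is respected
  g <- dplyr::group_by(
    tibble::tibble(
      subject = rep(c("a", "b"), each = 4),
      outcome = c("escape", "escape", "failure", "failure",
                  "failure", "failure", "failure", "escape"),
      latency_s = c(1, 2, 3, 3, 3, 3, 3, 1)
    ),
    subject
  )
  fg <- failure_stats(g)
  expect_equal(fg$pct_failures, c(50, 75))
})

test_that("learning curves increment on escapes, decrement on failures, hold on spontaneous", {
  lc <- learning_curve(c("escape", "escape", "failure", "spontaneous", "escape"))
  expect_equal(lc$value, c(1, 2, 1, 1, 2))
  expect_equal(learning_curve(rep("spontaneous", 6))$value, rep(0, 6))
  set.seed(13)
  s <- sample(c("escape", "failure", "spontaneous"), 1000, replace = TRUE)
  lc2 <- learning_curve(s)
  expect_equal(lc2$value[1000], sum(s == "escape") - sum(s == "failure"))
  expect_true(all(abs(diff(lc2$value)) <= 1))
  expect_error(learning_curve(c("escape", "jump")), "unknown outcome")
})

test_that("transition models match brute-force pair counting", {
  s <- c("escape", "escape", "failure", "escape", "spontaneous", "failure")
  m <- transition_model(s)
  expect_equal(m$probs["escape", ], c(escape = 1 / 3, failure = 1 / 3, spontaneous = 1 / 3))
  expect_equal(m$probs["failure", "escape"], 1)
  expect_equal(m$probs["spontaneous", "failure"], 1)
  expect_equal(unname(m$probs), unname(oracle_transitions(list(s))))

  # all-escape sequences: escape row defined, others undefined
  m2 <- transition_model(list(rep("escape", 5), rep("escape", 3)))
  expect_equal(m2$probs["escape", "escape"], 1)
  expect_true(all(is.na(m2$probs["failure", ])))

  # pooled counts are additive across animals
  s1 <- simulate_trial_sequence(balanced_matrix(), 50, seed = 1)
  s2 <- simulate_trial_sequence(balanced_matrix(), 80, seed = 2)
  pooled <- transition_model(list(s1, s2))
  expect_equal(pooled$counts,
               transition_model(s1)$counts + transition_model(s2)$counts)

  expect_error(transition_model(list()), "at least one")
  expect_error(transition_model(list("escape")), "no transitions")
})

test_that("transition estimation is consistent at 10,000 transitions", {
  m <- balanced_matrix()
  s <- simulate_trial_sequence(m, 10001, seed = 17)
  est <- transition_model(s)
  expect_lt(max(abs(est$probs - m)), 0.02)
  # the occurrence-normalized variant differs only through terminal trials
  expect_lt(max(abs(est$probs_by_occurrence - est$probs), na.rm = TRUE), 0.01)
})

test_that("model similarity is 1 minus the Frobenius norm of the difference", {
  m <- transition_model(simulate_trial_sequence(balanced_matrix(), 500, seed = 4))
  expect_equal(model_similarity(m, m), 1)
  # identity vs its cyclic row permutation: 1 - sqrt(6)
  id <- diag(3)
  dimnames(id) <- list(rownames(balanced_matrix()), colnames(balanced_matrix()))
  perm <- id[c(2, 3, 1), ]
  rownames(perm) <- rownames(id)
  expect_equal(model_similarity(id, perm), 1 - sqrt(6))
  # symmetry on random stochastic matrices
  set.seed(3)
  for (k in 1:10) {
    a <- matrix(rexp(9), 3); a <- a / rowSums(a)
    b <- matrix(rexp(9), 3); b <- b / rowSums(b)
    expect_equal(model_similarity(a, b), model_similarity(b, a))
  }
  # undefined rows are refused with the row named
  m2 <- transition_model(rep("escape", 5))
  expect_error(model_similarity(m2, m), "failure")
})

test_that("run-length statistics match an RLE oracle", {
  r <- run_length_stats(c("escape", "escape", "failure", "escape"))
  esc <- r[r$outcome == "escape", ]
  expect_equal(esc$mean_run, 1.5)
  expect_equal(esc$max_run, 2)

  rf <- run_length_stats(rep("failure", 10))
  expect_equal(rf$p_repeat[rf$outcome == "failure"], 1)
  expect_equal(rf$mean_run[rf$outcome == "failure"], 10)

  set.seed(31)
  s <- sample(c("escape", "failure", "spontaneous"), 400, replace = TRUE,
              prob = c(0.5, 0.4, 0.1))
  r2 <- run_length_stats(s)
  for (o in c("escape", "failure", "spontaneous")) {
    lens <- oracle_runs(s, o)
    row <- r2[r2$outcome == o, ]
    expect_equal(row$n_runs, length(lens))
    expect_equal(row$mean_run, mean(lens))
    expect_equal(row$max_run, max(lens))
    from <- s[-length(s)]; to <- s[-1]
    expect_equal(row$p_repeat, sum(from == o & to == o) / sum(from == o))
  }
})

test_that("the Gaussian failure-distribution fit is the closed-form MLE", {
  x <- c(40, 60, rep(50, 8))
  fit <- fit_failure_distribution(x)
  expect_equal(fit$mu, mean(x))
  expect_equal(fit$sigma, sqrt(mean((x - mean(x))^2)))
  expect_equal(sum(fit$histogram$count), length(x))
  expect_equal(sum(fit$histogram$density * fit$bin_width), 1)

  same <- fit_failure_distribution(rep(62, 5))
  expect_equal(same$mu, 62)
  expect_equal(same$sigma, 0)

  set.seed(8)
  big <- pmin(pmax(rnorm(4000, 70, 10), 0), 100)
  fb <- fit_failure_distribution(big)
  expect_lt(abs(fb$mu - 70), 1)
  expect_lt(abs(fb$sigma - 10), 1)

  expect_error(fit_failure_distribution(c(10, 20)), "at least 3")
})

test_that("the Normal MLE agrees with an independent distribution-fitting routine", {
  set.seed(12)
  x <- rnorm(60, 55, 12)
  fit <- fit_failure_distribution(x)
  ref <- fitdistrplus::fitdist(x, "norm", method = "mle")
  expect_equal(fit$mu, unname(ref$estimate["mean"]), tolerance = 1e-4)
  expect_equal(fit$sigma, unname(ref$estimate["sd"]), tolerance = 1e-4)
})

test_that("learning-curve endpoint ties out with failure statistics", {
  set.seed(99)
  for (k in 1:5) {
    s <- sample(c("escape", "failure", "spontaneous"), 200, replace = TRUE)
    lc <- learning_curve(s)
    ns <- sum(s != "spontaneous")
    frac_fail <- sum(s == "failure") / ns
    expect_equal(lc$value[200], round(ns * (1 - 2 * frac_fail)))
  }
})

test_that("ketamine-like matrices sit closer to baseline than helpless ones", {
  cfg <- test_config(n_subjects = 4, trials_per_session = 60)
  coh <- simulate_cohort(cfg)
  models <- lapply(c("baseline", "LH", "LH+KET"), function(cond) {
    transition_model(coh$trials[coh$trials$condition == cond, ])
  })
  names(models) <- c("baseline", "LH", "LH+KET")
  expect_gt(
    model_similarity(models$baseline, models$`LH+KET`),
    model_similarity(models$baseline, models$LH)
  )
})
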