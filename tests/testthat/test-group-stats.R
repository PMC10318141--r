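test_that("phase bins partition the 19 trials as published", {
  bins <- phase_bins()
  expect_identical(sort(unlist(bins, use.names = FALSE)), 1:19)
  tab <- assign_phase_bins(data.frame(trial_order = 1:19))
  expect_equal(as.character(tab$bin[c(1, 6, 10, 14, 19)]),
               c("baseline", "adapt1", "adapt2", "adapt3", "post"))
  expect_error(assign_phase_bins(data.frame(trial_order = 20)),
               "out of range")
})

test_that("phase summaries use between-participant standard errors", {
  d <- data.frame(participant_id = rep(c("a", "b"), each = 4),
                  group = "young", trial_order = rep(1:4, 2),
                  value = c(rep(100, 4), rep(120, 4)))
  s <- phase_summary(d, "value")
  expect_equal(s$mean, 110)
  expect_equal(s$se, sd(c(100, 120)) / sqrt(2))   # = 10
  expect_true(s$se_defined)
  # single participant: SE undefined, flagged and reported as 0
  s1 <- phase_summary(d[d$participant_id == "a", ], "value")
  expect_equal(s1$se, 0)
  expect_false(s1$se_defined)
})

test_that("centralization demeans per participant and is idempotent", {
  set.seed(71)
  d <- data.frame(participant_id = rep(sprintf("p%d", 1:6), each = 12),
                  x = rnorm(72), y = rnorm(72))
  d$x <- d$x + rep(rnorm(6, 0, 50), each = 12)   # participant offsets
  c1 <- centralize(d, c("x", "y"))
  means <- tapply(c1$x, c1$participant_id, mean)
  expect_true(all(abs(means) < 1e-12))
  c2 <- centralize(c1, c("x", "y"))
  expect_equal(c1$x, c2$x)
  # adding a participant-specific constant changes nothing after centering
  d2 <- d; d2$x <- d2$x + rep(seq(100, 600, 100), each = 12)
  expect_equal(centralize(d2, "x")$x, c1$x)
})

test_that("centralized correlation equals the two-stage demeaning oracle", {
  set.seed(72)
  n_p <- 8
  d <- data.frame(participant_id = rep(sprintf("p%d", 1:n_p), each = 10))
  d$x <- rnorm(80) + rep(rnorm(n_p, 0, 5), each = 10)
  d$y <- -0.6 * d$x + rnorm(80) + rep(rnorm(n_p, 0, 5), each = 10)
  cc <- centralize(d, c("x", "y"))
  r_pkg <- cor(cc$x, cc$y)
  # oracle: demean within participant by explicit loop, then pool
  xs <- ys <- c()
  for (p in unique(d$participant_id)) {
    i <- d$participant_id == p
    xs <- c(xs, d$x[i] - mean(d$x[i]))
    ys <- c(ys, d$y[i] - mean(d$y[i]))
  }
  expect_equal(r_pkg, cor(xs, ys), tolerance = 1e-12)
})

test_that("groupwise Pearson reports r, df = n - 2 and p", {
  d <- data.frame(group = rep("older", 20), x = 1:20, y = -(1:20))
  res <- pearson_by_group(d, "x", "y")
  expect_equal(res$r, -1)
  expect_equal(res$df, 18)
  d2 <- data.frame(group = "g", x = c(1, 2), y = c(2, 1))
  expect_error(pearson_by_group(d2, "x", "y"), "fewer than 3")
})

test_that("model fits satisfy the information-criterion identities", {
  set.seed(73)
  d <- simulate_cohort_metrics(n_older = 12, n_young = 10)
  mc <- suppressWarnings(model_comparison_table(d))
  for (f in mc$fits) {
    expect_equal(f$deviance, -2 * f$loglik)
    expect_equal(f$aic, f$deviance + 2 * f$df)
    expect_equal(f$bic, f$deviance + f$df * log(f$n_obs))
  }
  # parameter counts follow the declared random-effects structures
  expect_equal(unname(vapply(mc$fits, function(f) f$df, numeric(1))),
               c(7, 8, 7, 8, 7, 11))
})

test_that("the gaze-target-lag coefficient is recovered from simulation", {
  set.seed(74)
  d <- simulate_cohort_metrics(b_gt = -0.7)
  fit <- suppressWarnings(fit_lag_model(d, lag_model_specs()$m3))
  b <- fit$fixed_estimates[["gt_lag_ms"]]
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))[["gt_lag_ms"]]
  expect_lt(abs(b - (-0.7)), 1.96 * se + 0.05)
})

test_that("likelihood-ratio comparison behaves at its boundaries", {
  set.seed(75)
  d <- simulate_cohort_metrics(n_older = 10, n_young = 8)
  specs <- lag_model_specs()
  f1 <- suppressWarnings(fit_lag_model(d, specs$m1))
  f2 <- suppressWarnings(fit_lag_model(d, specs$m2))
  self <- compare_models(f1, f1)
  expect_equal(self$chisq, 0)
  expect_equal(self$df_diff, 0)
  lrt <- compare_models(f1, f2)
  expect_equal(lrt$df_diff, 1)
  expect_gte(lrt$chisq, 0)
  expect_error(compare_models(f2, f1), "fewer parameters")
})

test_that("a true anticipation effect is detected with high power", {
  set.seed(76)
  expect_gte(lrt_rejection_rate(15, b_gt = -0.7), 0.9)
})

test_that("constant response collapses to zero slopes and variances", {
  set.seed(77)
  d <- simulate_cohort_metrics(n_older = 6, n_young = 6)
  d$tc_lag_ms <- 50
  fit <- suppressWarnings(fit_lag_model(d, lag_model_specs()$m3))
  expect_lt(abs(fit$fixed_estimates[["trial_order"]]), 1e-6)
  expect_lt(abs(fit$fixed_estimates[["gt_lag_ms"]]), 1e-6)
})
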