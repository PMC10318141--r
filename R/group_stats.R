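#' Phase bins over the 19-trial session
#'
#' The test phases are divided into five bins for group summaries: baseline
#' (trials 1-4), three equal adaptation bins (5-8, 9-12, 13-16), and post-test
#' (17-19). The bins partition trial orders 1..19.
#'
#' @return named list mapping bin label to trial orders.
#' @export
phase_bins <- function() {
  list(baseline = 1:4, adapt1 = 5:8, adapt2 = 9:12, adapt3 = 13:16,
       post = 17:19)
}

#' Assign phase-bin labels to a metrics table
#'
#' @param metrics data.frame with a `trial_order` column in 1..19.
#' @return the table with a `bin` factor column added.
#' @export
assign_phase_bins <- function(metrics) {
  bins <- phase_bins()
  lookup <- rep(names(bins), lengths(bins))[order(unlist(bins))]
  if (any(metrics$trial_order < 1 | metrics$trial_order > length(lookup)))
    stop("trial_order out of range 1..", length(lookup))
  metrics$bin <- factor(lookup[metrics$trial_order], levels = names(bins))
  metrics
}

#' Group x bin summary of a metric
#'
#' Two-stage summary: first average the variable within participant and cell,
#' then take the mean and the between-participant standard error
#' (SD / sqrt(n participants)) per group x bin cell, matching error bars of
#' +/- 1 SE of means across participants. Cells with a single participant get
#' SE = 0 and `se_defined = FALSE`.
#'
#' @param metrics a binned metrics table (see [assign_phase_bins()]).
#' @param variable name of the metric column to summarise.
#' @return data.frame with `group`, `bin`, `mean`, `se`, `n`, `se_defined`.
#' @export
phase_summary <- function(metrics, variable) {
  if (!variable %in% names(metrics)) stop("unknown variable: ", variable)
  if (!"bin" %in% names(metrics)) metrics <- assign_phase_bins(metrics)
  pm <- stats::aggregate(metrics[[variable]],
                         by = list(group = metrics$group, bin = metrics$bin,
                                   participant_id = metrics$participant_id),
                         FUN = mean, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(pm, list(pm$group, pm$bin),
                                     drop = TRUE), function(cell) {
    n <- nrow(cell)
    data.frame(group = cell$group[1], bin = cell$bin[1],
               mean = mean(cell$x), se = if (n > 1) stats::sd(cell$x) / sqrt(n)
               else 0,
               n = n, se_defined = n > 1)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$bin), ]
}

#' Within-participant centralization
#'
#' Subtracts each participant's own mean of the listed variables, removing
#' between-participant variation so that the remaining covariation is purely
#' within-participant. Idempotent.
#'
#' @param metrics data.frame with `participant_id`.
#' @param variables character vector of column names to centralize.
#' @return the table with the listed columns demeaned per participant.
#' @export
centralize <- function(metrics, variables) {
  for (v in variables) {
    if (!v %in% names(metrics)) stop("unknown variable: ", v)
    metrics[[v]] <- metrics[[v]] -
      stats::ave(metrics[[v]], metrics$participant_id, FUN = mean)
  }
  metrics
}

#' Pearson correlation between two metrics, by group
#'
#' @param metrics data.frame.
#' @param x,y column names.
#' @param by grouping column (default `"group"`).
#' @return data.frame with `group`, `r`, `df`, `p`, `n`.
#' @export
pearson_by_group <- function(metrics, x, y, by = "group") {
  out <- do.call(rbind, lapply(split(metrics, metrics[[by]]), function(g) {
    ok <- stats::complete.cases(g[[x]], g[[y]])
    if (sum(ok) < 3) stop("fewer than 3 complete pairs in a group")
    ct <- stats::cor.test(g[[x]][ok], g[[y]][ok])
    data.frame(group = g[[by]][1], r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value, n = sum(ok))
  }))
  rownames(out) <- NULL
  out
}

#' The candidate mixed-model set for target-cursor lag
#'
#' Six linear mixed models for per-trial target-cursor lag, all controlling
#' for trial order (TO, the within-session learning trend) and differing in
#' whether participant age and/or the anticipation and execution measures
#' (gaze-target lag, GT_lag; lag-corrected random error, RE) enter as fixed
#' effects. All models carry correlated random intercept and trial-order
#' slope per participant; the full model additionally carries a random
#' GT_lag slope, the structure implied by its parameter count.
#'
#' @return named list of model specs (`name`, `fixed` formula text, `random`
#'   formula text).
#' @export
lag_model_specs <- function() {
  base_re <- "(1 + trial_order | participant_id)"
  rich_re <- "(1 + trial_order + gt_lag_ms | participant_id)"
  list(
    m1 = list(name = "Model 1: TC_lag ~ age + TO",
              fixed = "tc_lag_ms ~ age + trial_order", random = base_re),
    m2 = list(name = "Model 2: TC_lag ~ age + TO + GT_lag",
              fixed = "tc_lag_ms ~ age + trial_order + gt_lag_ms",
              random = base_re),
    m3 = list(name = "Model 3: TC_lag ~ TO + GT_lag",
              fixed = "tc_lag_ms ~ trial_order + gt_lag_ms",
              random = base_re),
    m4 = list(name = "Model 4: TC_lag ~ age + TO + RE",
              fixed = "tc_lag_ms ~ age + trial_order + random_error_deg",
              random = base_re),
    m5 = list(name = "Model 5: TC_lag ~ TO + RE",
              fixed = "tc_lag_ms ~ trial_order + random_error_deg",
              random = base_re),
    m6 = list(name = "Model 6: TC_lag ~ TO + RE + GT_lag",
              fixed = "tc_lag_ms ~ trial_order + random_error_deg + gt_lag_ms",
              random = rich_re))
}

#' Fit one mixed model of the candidate set
#'
#' Maximum-likelihood fit (not REML, because the models are compared through
#' likelihood ratios across different fixed-effect sets) of a linear mixed
#' model with per-participant random effects.
#'
#' @param data per-trial metrics table with `tc_lag_ms`, `trial_order`,
#'   `gt_lag_ms`, `random_error_deg`, `age`, `participant_id` as required by
#'   the spec.
#' @param spec one element of [lag_model_specs()], or a list with `name`,
#'   `fixed`, `random`.
#' @return list of class `lag_model_fit`: `spec`, `fit` (the `lmerMod`),
#'   `df`, `loglik`, `deviance`, `aic`, `bic`, `fixed_estimates`, `singular`.
#' @export
fit_lag_model <- function(data, spec) {
  f <- stats::as.formula(paste(spec$fixed, "+", spec$random))
  fit <- suppressMessages(lme4::lmer(
    f, data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular mixed-model fit: ", spec$name)
  ll <- stats::logLik(fit)
  structure(list(spec = spec, fit = fit,
                 df = attr(ll, "df"),
                 loglik = as.numeric(ll),
                 deviance = -2 * as.numeric(ll),
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 fixed_estimates = lme4::fixef(fit),
                 n_obs = stats::nobs(fit),
                 singular = singular),
            class = "lag_model_fit")
}

#' @export
print.lag_model_fit <- function(x, ...) {
  cat(x$spec$name, "\n")
  cat(sprintf("  df %d  logLik %.1f  deviance %.1f  AIC %.1f  BIC %.1f\n",
              x$df, x$loglik, x$deviance, x$aic, x$bic))
  invisible(x)
}

#' Likelihood-ratio comparison of two nested mixed models
#'
#' Chi-square test on the deviance difference of two maximum-likelihood fits
#' of nested models on the same rows.
#'
#' @param fit_small,fit_large `lag_model_fit` objects; `fit_small` must be
#'   nested in `fit_large`.
#' @return list of class `lrt_result` with `chisq`, `df_diff`, `p_value`.
#' @export
compare_models <- function(fit_small, fit_large) {
  if (fit_small$n_obs != fit_large$n_obs)
    stop("models were fitted to different numbers of rows")
  if (fit_large$df < fit_small$df)
    stop("fit_large has fewer parameters than fit_small; not nested")
  chisq <- max(0, fit_small$deviance - fit_large$deviance)
  df_diff <- fit_large$df - fit_small$df
  p <- if (df_diff == 0) NA_real_ else
    stats::pchisq(chisq, df_diff, lower.tail = FALSE)
  structure(list(chisq = chisq, df_diff = df_diff, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.2f, df = %d, p = %.3g\n",
              x$chisq, x$df_diff, x$p_value))
  invisible(x)
}

#' Fit the full candidate model set and tabulate it
#'
#' @param data per-trial metrics with the model variables.
#' @param specs list of model specs (default [lag_model_specs()]).
#' @return list with `fits` (named list of `lag_model_fit`) and `table`
#'   (data.frame with columns Model, df, logLik, deviance, AIC, BIC).
#' @export
model_comparison_table <- function(data, specs = lag_model_specs()) {
  fits <- lapply(specs, function(s) fit_lag_model(data, s))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(Model = f$spec$name, df = f$df, logLik = f$loglik,
               deviance = f$deviance, AIC = f$aic, BIC = f$bic)))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Simulate a cohort metrics table from a mixed-model structure
#'
#' Generates per-trial adaptation-phase rows directly from the generative
#' structure of the gaze-target-lag model: per participant, an age (older
#' group 60-73 years, young 19-27), a participant-mean gaze-target lag, and
#' correlated random intercept and trial-order slope; per trial, a
#' gaze-target lag around the participant mean and a target-cursor lag
#'
#' `tc = b0 + b_to * TO + b_gt * gt + u0_i + u1_i * TO + e`.
#'
#' Used by the statistical-recovery tests: with `b_gt = 0` the data satisfy
#' the null of no anticipation effect.
#'
#' @param n_older,n_young participants per group.
#' @param trial_orders trial orders of the simulated rows (adaptation trials
#'   5..16 by default).
#' @param b0,b_to,b_gt fixed effects (ms, ms/trial, ms/ms).
#' @param sd_u0,sd_u1,cor_u random-effect SDs and correlation.
#' @param gt_mean_older,gt_mean_young,gt_sd_between,gt_sd_within gaze-target
#'   lag population (ms).
#' @param sigma residual SD (ms).
#' @param re_mean_deg,re_sd_deg lag-corrected random-error population (deg),
#'   filled in so the full model set is estimable.
#' @param b_re fixed effect of random error on the lag (ms/deg).
#' @return data.frame with `participant_id`, `group`, `age`, `trial_order`,
#'   `gt_lag_ms`, `random_error_deg`, `tc_lag_ms`.
#' @export
simulate_cohort_metrics <- function(n_older = 29, n_young = 23,
                                    trial_orders = 5:16,
                                    b0 = 150, b_to = -1.5, b_gt = -0.7,
                                    sd_u0 = 25, sd_u1 = 1.5, cor_u = -0.3,
                                    gt_mean_older = 60, gt_mean_young = 100,
                                    gt_sd_between = 30, gt_sd_within = 25,
                                    sigma = 20,
                                    re_mean_deg = 0.8, re_sd_deg = 0.25,
                                    b_re = 0) {
  n <- n_older + n_young
  group <- rep(c("older", "young"), c(n_older, n_young))
  age <- c(round(stats::runif(n_older, 60, 73)),
           round(stats::runif(n_young, 19, 27)))
  Sigma_u <- matrix(c(sd_u0^2, cor_u * sd_u0 * sd_u1,
                      cor_u * sd_u0 * sd_u1, sd_u1^2), 2)
  L <- chol(Sigma_u)
  u <- matrix(stats::rnorm(2 * n), n) %*% L
  gt_part <- ifelse(group == "older", gt_mean_older, gt_mean_young) +
    stats::rnorm(n, 0, gt_sd_between)
  rows <- lapply(seq_len(n), function(i) {
    to <- trial_orders
    gt <- gt_part[i] + stats::rnorm(length(to), 0, gt_sd_within)
    re <- pmax(0.05, stats::rnorm(length(to), re_mean_deg, re_sd_deg))
    tc <- b0 + b_to * to + b_gt * gt + b_re * re +
      u[i, 1] + u[i, 2] * to + stats::rnorm(length(to), 0, sigma)
    data.frame(participant_id = sprintf("p%02d", i), group = group[i],
               age = age[i], trial_order = to, gt_lag_ms = gt,
               random_error_deg = re, tc_lag_ms = tc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power / type-I error of the LRT for the gaze-target-lag effect
#'
#' Repeatedly simulates cohorts with [simulate_cohort_metrics()] and tests
#' the fixed gaze-target-lag effect by likelihood ratio (model with TO and
#' age vs the same model plus GT_lag, both with random intercept + TO slope).
#'
#' @param n_rep number of replicates.
#' @param alpha nominal level.
#' @param ... passed to [simulate_cohort_metrics()] (`b_gt = 0` gives the
#'   null).
#' @return rejection rate across replicates.
#' @export
lrt_rejection_rate <- function(n_rep = 100, alpha = 0.05, ...) {
  specs <- lag_model_specs()
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_cohort_metrics(...)
    f1 <- suppressWarnings(fit_lag_model(d, specs$m1))
    f2 <- suppressWarnings(fit_lag_model(d, specs$m2))
    rej[r] <- compare_models(f1, f2)$p_value < alpha
  }
  mean(rej)
}
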