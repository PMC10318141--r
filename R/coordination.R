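#' Cross-correlation lag between two aligned series
#'
#' Finds the integer-sample shift maximising the Pearson correlation between
#' `reference(t)` and `follower(t + s)`, scanning `s` in
#' `[-max_lag_ms, max_lag_ms]`. The sign convention is that a positive result
#' means the follower trails the reference (e.g. the cursor moves behind the
#' target). Ties are broken toward the smallest absolute lag. Each shift uses
#' the overlapping window only, with means and variances recomputed per shift.
#'
#' @param reference,follower equal-length series on the same uniform grid.
#' @param max_lag_ms half-width of the search window (ms).
#' @param fs sampling rate (Hz); at 1000 Hz the lag resolution is 1 ms.
#' @return lag in ms (positive = follower behind reference).
#' @export
xcorr_lag <- function(reference, follower, max_lag_ms = 1000, fs = 1000) {
  n <- length(reference)
  if (length(follower) != n) stop("series lengths differ")
  if (stats::sd(reference) == 0 || stats::sd(follower) == 0)
    stop("zero-variance input; correlation undefined")
  max_s <- round(max_lag_ms * fs / 1000)
  if (max_s >= n) stop("max_lag_ms must be shorter than the series")
  shifts <- -max_s:max_s

  # cross sums for every shift at once via FFT; per-shift window means and
  # variances from cumulative sums, giving the exact Pearson r per shift.
  # Global demeaning leaves every per-window Pearson r unchanged but keeps
  # the cumulative sums well conditioned.
  reference <- reference - mean(reference)
  follower <- follower - mean(follower)
  n2 <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(reference, rep(0, n2 - n)))
  Y <- stats::fft(c(follower, rep(0, n2 - n)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / n2
  cc_idx <- ifelse(shifts > 0, n2 - shifts + 1, 1 - shifts)
  sum_ab <- cc[cc_idx]

  # zero-padded cumulative sums: cs[k + 1] = sum of the first k samples
  cs_a <- c(0, cumsum(reference)); cs_a2 <- c(0, cumsum(reference^2))
  cs_b <- c(0, cumsum(follower));  cs_b2 <- c(0, cumsum(follower^2))
  m <- n - abs(shifts)
  # s >= 0: a = ref[1..n-s],      b = fol[1+s..n]
  # s <  0: a = ref[1-s..n],      b = fol[1..n+s]
  sum_a <- ifelse(shifts >= 0, cs_a[m + 1], cs_a[n + 1] - cs_a[n - m + 1])
  sum_a2 <- ifelse(shifts >= 0, cs_a2[m + 1],
                   cs_a2[n + 1] - cs_a2[n - m + 1])
  sum_b <- ifelse(shifts >= 0, cs_b[n + 1] - cs_b[n - m + 1], cs_b[m + 1])
  sum_b2 <- ifelse(shifts >= 0, cs_b2[n + 1] - cs_b2[n - m + 1],
                   cs_b2[m + 1])
  var_a <- sum_a2 - sum_a^2 / m
  var_b <- sum_b2 - sum_b^2 / m
  denom <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  r <- ifelse(denom > 0, (sum_ab - sum_a * sum_b / m) / denom, -Inf)

  best <- max(r)
  cand <- shifts[r >= best - 1e-9]
  s_hat <- cand[which.min(abs(cand))]
  s_hat * 1000 / fs
}

#' Root-mean-square tracking error in degrees
#'
#' RMSE between target and cursor positions, converted from pixels to degrees
#' of visual angle.
#'
#' @param target,cursor aligned position series (px).
#' @param screen a [screen_geometry()].
#' @return RMSE in degrees.
#' @export
tracking_rmse <- function(target, cursor, screen = screen_geometry()) {
  if (length(target) != length(cursor)) stop("series lengths differ")
  sqrt(mean((target - cursor)^2)) / screen$px_per_deg
}

#' Lag-corrected random error
#'
#' Estimates the target-cursor lag by cross-correlation, advances the cursor
#' by that lag, truncates both series to the overlapping window, and returns
#' the residual RMSE. This removes the systematic error component due to the
#' cursor trailing the target and leaves the random error of motor execution.
#'
#' @param target,cursor aligned series (px).
#' @param screen a [screen_geometry()].
#' @param max_lag_ms lag search window.
#' @param fs sampling rate (Hz).
#' @return list with `tc_lag_ms` and `random_error_deg`.
#' @export
random_error <- function(target, cursor, screen = screen_geometry(),
                         max_lag_ms = 1000, fs = 1000) {
  lag_ms <- xcorr_lag(target, cursor, max_lag_ms, fs)
  s <- round(lag_ms * fs / 1000)
  n <- length(target)
  if (abs(s) >= n) stop("estimated lag spans the whole series")
  if (s >= 0) {
    tt <- target[seq_len(n - s)]
    cc <- cursor[(1 + s):n]
  } else {
    tt <- target[(1 - s):n]
    cc <- cursor[seq_len(n + s)]
  }
  list(tc_lag_ms = lag_ms,
       random_error_deg = tracking_rmse(tt, cc, screen))
}

#' Per-trial eye-hand coordination metrics
#'
#' Computes the complete per-trial metric row: target-cursor RMSE (deg),
#' target-cursor lag and lag-corrected random error, gaze-cursor and
#' gaze-target lags on the saccade-excised pursuit trace, saccade rate, and
#' mean pupil area. Sign conventions: `tc_lag_ms` positive = cursor behind
#' target; `gc_lag_ms` positive = gaze ahead of cursor; `gt_lag_ms` positive
#' = gaze ahead of target.
#'
#' @param aligned an `aligned_trial` from [preprocess_trial()].
#' @param events an `event_set` from [detect_events()].
#' @param screen a [screen_geometry()].
#' @param max_lag_ms lag search half-window (ms).
#' @param fs sampling rate (Hz).
#' @return one-row data.frame of class `trial_metrics`.
#' @export
trial_metrics <- function(aligned, events, screen = screen_geometry(),
                          max_lag_ms = 1000, fs = 1000) {
  pursuit <- excise_and_fill(aligned$gaze_x_px, events, aligned$t_ms)
  re <- random_error(aligned$target_x_px, aligned$cursor_x_px, screen,
                     max_lag_ms, fs)
  dur_s <- (max(aligned$t_ms) - min(aligned$t_ms) + 1000 / fs) / 1000
  out <- data.frame(
    participant_id = aligned$participant_id,
    group = aligned$group,
    trial_order = aligned$trial_order,
    phase = aligned$phase,
    rmse_deg = tracking_rmse(aligned$target_x_px, aligned$cursor_x_px,
                             screen),
    tc_lag_ms = re$tc_lag_ms,
    gc_lag_ms = xcorr_lag(pursuit, aligned$cursor_x_px, max_lag_ms, fs),
    gt_lag_ms = xcorr_lag(pursuit, aligned$target_x_px, max_lag_ms, fs),
    random_error_deg = re$random_error_deg,
    saccade_rate_hz = saccade_rate(events, dur_s),
    mean_pupil_px = mean_pupil(aligned$pupil_area_px, aligned$valid),
    stringsAsFactors = FALSE)
  class(out) <- c("trial_metrics", "data.frame")
  out
}

#' Metrics for every trial of a session
#'
#' Runs preprocessing, event detection and metric computation over all trials
#' of a session and binds the per-trial rows.
#'
#' @param session a `session` (list of `trial_trace`).
#' @param config a [protocol_config()].
#' @param max_lag_ms lag search half-window (ms).
#' @return data.frame with one `trial_metrics` row per trial.
#' @export
session_metrics <- function(session, config = protocol_config(),
                            max_lag_ms = 1000) {
  rows <- lapply(session, function(tr) {
    al <- preprocess_trial(tr, config)
    ev <- detect_events(al)
    trial_metrics(al, ev, config$screen, max_lag_ms, config$gaze_rate_hz)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
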