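#' Iterative peak-velocity threshold estimation
#'
#' Data-driven estimation of the saccade peak-detection threshold: starting
#' from `init_deg_s` (200 deg/s), repeatedly compute the mean and SD of all
#' plausible speed samples below the current threshold and update the
#' threshold to `mean + k * SD` (k = 6), until two successive thresholds
#' differ by less than `tol_deg_s` (1 deg/s). If an update leaves the
#' sub-threshold set empty (degenerate, e.g. constant-speed traces) the last
#' computed threshold is returned.
#'
#' @param kin a [compute_kinematics()] result.
#' @param init_deg_s initial detection threshold (deg/s).
#' @param k SD multiplier of the update.
#' @param tol_deg_s convergence tolerance (deg/s).
#' @param max_iter iteration safety bound.
#' @return list with `threshold_deg_s`, `n_iterations`, and
#'   `onset_threshold_deg_s` (mean + 3 SD of the converged sub-threshold
#'   samples, used as the saccade onset criterion).
#' @export
estimate_peak_threshold <- function(kin, init_deg_s = 200, k = 6,
                                    tol_deg_s = 1, max_iter = 100) {
  v <- kin$speed_deg_s[kin$plausible]
  if (!any(v < init_deg_s))
    stop("no plausible samples below the initial threshold; ",
         "trace appears saturated")
  pt <- init_deg_s
  onset_thr <- NA_real_
  for (i in seq_len(max_iter)) {
    sub <- v[v < pt]
    if (length(sub) == 0) return(list(threshold_deg_s = pt, n_iterations = i,
                                      onset_threshold_deg_s = onset_thr))
    m <- mean(sub); s <- stats::sd(sub)
    if (is.na(s)) s <- 0
    new_pt <- m + k * s
    onset_thr <- m + 3 * s
    if (abs(new_pt - pt) < tol_deg_s)
      return(list(threshold_deg_s = new_pt, n_iterations = i,
                  onset_threshold_deg_s = onset_thr))
    pt <- new_pt
  }
  warning("peak-threshold iteration did not converge in ", max_iter,
          " iterations")
  list(threshold_deg_s = pt, n_iterations = max_iter,
       onset_threshold_deg_s = onset_thr)
}

# First index at/before `from` (searching backward) where speed drops below
# `thr` and the following `run` samples are non-decreasing in time (i.e. the
# speed was locally monotonically rising into the saccade).
search_onset <- function(speed, from, thr, run = 5) {
  i <- from
  while (i >= 1) {
    if (speed[i] < thr) {
      hi <- min(length(speed), i + run - 1)
      if (all(diff(speed[i:hi]) >= 0) || i == 1) return(i)
    }
    i <- i - 1
  }
  1L
}

# First index at/after `from` where speed drops below `thr` and the preceding
# `run` samples are non-increasing (speed decayed monotonically into offset).
search_offset <- function(speed, from, thr, run = 5) {
  n <- length(speed)
  i <- from
  first_below <- NA_integer_
  while (i <= n) {
    if (speed[i] < thr) {
      if (is.na(first_below)) first_below <- i
      lo <- max(1, i - run + 1)
      if (all(diff(speed[lo:i]) <= 0) || i == n) return(i)
    }
    i <- i + 1
  }
  if (!is.na(first_below)) first_below else n
}

#' Detect saccades with the adaptive velocity-threshold algorithm
#'
#' Finds local speed maxima above the converged peak threshold, then for each
#' peak searches backward for the onset (first sample below the global
#' noise criterion, mean + 3 SD of sub-threshold samples, where the speed was
#' locally monotonically decreasing toward the past) and forward for the
#' offset (first sample below a weighted combination of the onset criterion
#' and a locally adaptive noise factor computed over the window preceding the
#' onset, with a local monotonic decay behind it). Events separated by less
#' than `merge_gap_ms` are merged; events shorter than `min_dur_ms` are
#' discarded.
#'
#' @param kin a [compute_kinematics()] result.
#' @param threshold output of [estimate_peak_threshold()] (or a number, in
#'   which case the onset criterion is recomputed from sub-threshold samples).
#' @param t_ms time stamps of the kinematic samples.
#' @param w_onset,w_local weights of the offset criterion (default 0.7 / 0.3).
#' @param local_window_ms window before onset for the local noise factor.
#' @param min_dur_ms minimum saccade duration.
#' @param merge_gap_ms events closer than this are merged.
#' @param mono_run_samples run length of the monotonicity checks.
#' @return list of class `event_set`: data.frame `saccades` (`onset_ms`,
#'   `offset_ms`, `peak_speed_deg_s`, `glissade_offset_ms`), data.frame
#'   `missing_intervals`, `final_threshold_deg_s`, `n_iterations`.
#' @export
detect_saccades <- function(kin, threshold, t_ms,
                            w_onset = 0.7, w_local = 0.3,
                            local_window_ms = 40, min_dur_ms = 10,
                            merge_gap_ms = 20, mono_run_samples = 5) {
  if (is.numeric(threshold)) {
    v <- kin$speed_deg_s[kin$plausible]
    sub <- v[v < threshold]
    threshold <- list(threshold_deg_s = threshold, n_iterations = 0L,
                      onset_threshold_deg_s = mean(sub) + 3 * stats::sd(sub))
  }
  pt <- threshold$threshold_deg_s
  onset_thr <- threshold$onset_threshold_deg_s
  speed <- kin$speed_deg_s
  n <- length(speed)
  dt <- if (n > 1) t_ms[2] - t_ms[1] else 1
  local_win <- max(1, round(local_window_ms / dt))

  over <- speed > pt & kin$plausible
  # local maxima above threshold
  peaks <- which(over &
                   c(TRUE, diff(speed) > 0) &
                   c(speed[-n] >= speed[-1], TRUE))
  events <- list()
  last_off <- 0L
  for (p in peaks) {
    if (p <= last_off) next            # peak inside the previous event
    on <- search_onset(speed, p, onset_thr, mono_run_samples)
    pre <- speed[max(1, on - local_win):max(1, on - 1)]
    local_noise <- if (length(pre) > 1)
      mean(pre) + 3 * stats::sd(pre) else onset_thr
    off_thr <- w_onset * onset_thr + w_local * local_noise
    off <- search_offset(speed, p, off_thr, mono_run_samples)
    last_off <- off
    events[[length(events) + 1]] <-
      c(on = on, off = off,
        peak = max(speed[on:off]), off_thr = off_thr)
  }
  if (length(events) == 0) {
    sac <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      peak_speed_deg_s = numeric(0),
                      glissade_offset_ms = numeric(0),
                      offset_threshold_deg_s = numeric(0))
  } else {
    ev <- do.call(rbind, events)
    # merge events separated by less than merge_gap_ms
    merged <- list(ev[1, ])
    if (nrow(ev) > 1) for (r in 2:nrow(ev)) {
      prev <- merged[[length(merged)]]
      if ((ev[r, "on"] - prev["off"]) * dt < merge_gap_ms) {
        prev["off"] <- ev[r, "off"]
        prev["peak"] <- max(prev["peak"], ev[r, "peak"])
        merged[[length(merged)]] <- prev
      } else merged[[length(merged) + 1]] <- ev[r, ]
    }
    ev <- do.call(rbind, merged)
    dur_ok <- (ev[, "off"] - ev[, "on"]) * dt >= min_dur_ms
    ev <- ev[dur_ok, , drop = FALSE]
    sac <- data.frame(onset_ms = t_ms[ev[, "on"]],
                      offset_ms = t_ms[ev[, "off"]],
                      peak_speed_deg_s = ev[, "peak"],
                      glissade_offset_ms = rep(NA_real_, nrow(ev)),
                      offset_threshold_deg_s = ev[, "off_thr"])
  }
  missing <- valid_gaps(kin$plausible & !is.na(speed), t_ms)
  structure(list(saccades = sac, missing_intervals = missing,
                 final_threshold_deg_s = pt,
                 n_iterations = threshold$n_iterations),
            class = "event_set")
}

# Runs of FALSE in a logical mask, as (start_ms, end_ms) intervals.
valid_gaps <- function(valid, t_ms) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bad <- !r$values
  data.frame(start_ms = t_ms[starts[bad]], end_ms = t_ms[ends[bad]])
}

#' Detect glissades following saccades
#'
#' Examines a bounded window (40 ms by default) after each saccade offset; if
#' the speed re-exceeds that saccade's offset criterion, the event is extended
#' as a glissade ending at the first sustained monotonic rise after the last
#' local speed peak inside the window (capped at the window end). The
#' glissade offset is recorded on the parent saccade.
#'
#' @param kin a [compute_kinematics()] result.
#' @param events an `event_set` from [detect_saccades()].
#' @param t_ms time stamps.
#' @param window_ms glissade search window after saccade offset.
#' @param mono_run_samples run length of the monotonicity check.
#' @return the `event_set` with `glissade_offset_ms` filled in where found.
#' @export
detect_glissades <- function(kin, events, t_ms, window_ms = 40,
                             mono_run_samples = 5) {
  sac <- events$saccades
  if (nrow(sac) == 0) return(events)
  speed <- kin$speed_deg_s
  n <- length(speed)
  dt <- if (n > 1) t_ms[2] - t_ms[1] else 1
  for (i in seq_len(nrow(sac))) {
    off_idx <- which.min(abs(t_ms - sac$offset_ms[i]))
    w_end <- min(n, off_idx + round(window_ms / dt))
    if (w_end <= off_idx + 2) next
    win <- (off_idx + 1):w_end
    crit <- sac$offset_threshold_deg_s[i]
    if (!any(speed[win] > crit)) next
    # last local speed peak inside the window
    loc <- win[-c(1, length(win))]
    pk <- loc[speed[loc] > speed[loc - 1] & speed[loc] >= speed[loc + 1] &
                speed[loc] > crit]
    start_from <- if (length(pk)) max(pk) else win[which.max(speed[win])]
    g_end <- w_end
    j <- start_from
    while (j <= w_end - mono_run_samples + 1) {
      if (all(diff(speed[j:(j + mono_run_samples - 1)]) >= 0)) {
        g_end <- j; break
      }
      j <- j + 1
    }
    sac$glissade_offset_ms[i] <- t_ms[min(g_end, w_end)]
  }
  events$saccades <- sac
  events
}

#' Excise events from the gaze trace and fill by linear interpolation
#'
#' Replaces samples inside each saccade (through its glissade offset when
#' present) and inside missing-data intervals with a straight line between the
#' nearest samples outside the interval, yielding the pursuit-only trace used
#' for the gaze lag analyses. Samples outside event intervals are never
#' changed; intervals touching the series edge degenerate to a boundary-value
#' hold.
#'
#' @param x gaze position series.
#' @param events an `event_set`.
#' @param t_ms time stamps of `x`.
#' @param pad_ms extra margin excised on each side of every event.
#' @return series of the same length with events replaced by interpolation.
#' @export
excise_and_fill <- function(x, events, t_ms, pad_ms = 0) {
  sac <- events$saccades
  ints <- rbind(
    if (nrow(sac) > 0)
      data.frame(s = sac$onset_ms - pad_ms,
                 e = ifelse(is.na(sac$glissade_offset_ms), sac$offset_ms,
                            sac$glissade_offset_ms) + pad_ms)
    else NULL,
    if (nrow(events$missing_intervals) > 0)
      data.frame(s = events$missing_intervals$start_ms,
                 e = events$missing_intervals$end_ms)
    else NULL)
  if (is.null(ints) || nrow(ints) == 0) return(x)
  # merge overlapping / adjacent intervals so fills never read filled samples
  ints <- ints[order(ints$s), , drop = FALSE]
  merged <- ints[1, ]
  if (nrow(ints) > 1) for (r in 2:nrow(ints)) {
    k <- nrow(merged)
    if (ints$s[r] <= merged$e[k]) merged$e[k] <- max(merged$e[k], ints$e[r])
    else merged <- rbind(merged, ints[r, ])
  }
  y <- x
  n <- length(x)
  for (r in seq_len(nrow(merged))) {
    inside <- which(t_ms >= merged$s[r] & t_ms <= merged$e[r])
    if (length(inside) == 0) next
    lo <- min(inside) - 1L
    hi <- max(inside) + 1L
    while (lo >= 1 && is.na(y[lo])) lo <- lo - 1L   # skip unfilled gaps
    while (hi <= n && is.na(y[hi])) hi <- hi + 1L
    if (lo < 1 && hi > n) next
    if (lo < 1) { y[inside] <- y[hi] ; next }
    if (hi > n) { y[inside] <- y[lo] ; next }
    y[inside] <- y[lo] + (y[hi] - y[lo]) *
      (t_ms[inside] - t_ms[lo]) / (t_ms[hi] - t_ms[lo])
  }
  y
}

#' Saccade rate of a trial
#'
#' Number of detected saccades divided by the effective tracked duration.
#' Glissades are wobbles attached to a parent saccade and are not counted as
#' separate events by default; `include_glissades = TRUE` counts each
#' glissade as an additional event.
#'
#' @param events an `event_set`.
#' @param effective_duration_s analysed duration in seconds.
#' @param include_glissades count glissades as separate events.
#' @return rate in events per second.
#' @export
saccade_rate <- function(events, effective_duration_s,
                         include_glissades = FALSE) {
  if (effective_duration_s <= 0) stop("effective duration must be positive")
  n <- nrow(events$saccades)
  if (include_glissades)
    n <- n + sum(!is.na(events$saccades$glissade_offset_ms))
  n / effective_duration_s
}

#' Mean pupil area of a trial
#'
#' Mean over valid samples only; an all-invalid trial yields `NA` with a
#' warning.
#'
#' @param pupil_area_px pupil area series (px).
#' @param valid logical validity mask.
#' @return mean pupil area in pixels.
#' @export
mean_pupil <- function(pupil_area_px, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(pupil_area_px)
  ok <- valid & !is.na(pupil_area_px)
  if (!any(ok)) {
    warning("no valid pupil samples in trial")
    return(NA_real_)
  }
  mean(pupil_area_px[ok])
}

#' Run the full event-detection stage on an aligned trial
#'
#' @param aligned an `aligned_trial` from [preprocess_trial()].
#' @param init_deg_s,k,tol_deg_s threshold-iteration settings.
#' @param ... further arguments passed to [detect_saccades()].
#' @return an `event_set` with glissades annotated.
#' @export
detect_events <- function(aligned, init_deg_s = 200, k = 6, tol_deg_s = 1,
                          ...) {
  thr <- estimate_peak_threshold(aligned$kinematics, init_deg_s, k, tol_deg_s)
  ev <- detect_saccades(aligned$kinematics, thr, aligned$t_ms, ...)
  detect_glissades(aligned$kinematics, ev, aligned$t_ms)
}

#' Match detected events against ground truth
#'
#' Benchmarks a detector run against a table of true events by interval
#' overlap: a true event is recalled when at least one detected saccade
#' overlaps its span (through the glissade offset when present, padded by
#' `tol_ms`), and a detected event is a true positive when it overlaps some
#' true span. Also reports onset and offset timing errors over uniquely
#' matched pairs.
#'
#' @param truth data.frame with `onset_ms`, `offset_ms`, and optionally
#'   `glissade_offset_ms`.
#' @param events an `event_set`.
#' @param tol_ms overlap padding tolerance (ms).
#' @return list with `recall`, `precision`, `n_true`, `n_detected`,
#'   `onset_err_ms`, `offset_err_ms` (vectors over matched pairs).
#' @export
match_events <- function(truth, events, tol_ms = 10) {
  det <- events$saccades
  t_end <- if ("glissade_offset_ms" %in% names(truth))
    ifelse(is.na(truth$glissade_offset_ms), truth$offset_ms,
           truth$glissade_offset_ms) else truth$offset_ms
  d_end <- ifelse(is.na(det$glissade_offset_ms), det$offset_ms,
                  det$glissade_offset_ms)
  n_t <- nrow(truth); n_d <- nrow(det)
  recalled <- logical(n_t); tp <- logical(n_d)
  onset_err <- offset_err <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    ov <- which(det$onset_ms <= t_end[i] + tol_ms &
                  d_end >= truth$onset_ms[i] - tol_ms)
    if (length(ov)) {
      recalled[i] <- TRUE
      tp[ov] <- TRUE
      j <- ov[which.min(abs(det$onset_ms[ov] - truth$onset_ms[i]))]
      onset_err[i] <- det$onset_ms[j] - truth$onset_ms[i]
      offset_err[i] <- det$offset_ms[j] - truth$offset_ms[i]
    }
  }
  list(recall = if (n_t) mean(recalled) else NA_real_,
       precision = if (n_d) mean(tp) else NA_real_,
       n_true = n_t, n_detected = n_d,
       onset_err_ms = onset_err[recalled], offset_err_ms = offset_err[recalled])
}
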