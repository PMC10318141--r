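#' Zero-phase Butterworth low-pass filter
#'
#' Designs an order-`order` Butterworth low-pass and applies it forward and
#' backward (`signal::filtfilt`), which cancels the filter's phase response.
#' Any phase lag would bias the cross-correlation lags that are the pipeline's
#' primary outcome, so all position filtering in the package is zero-phase.
#' Because the two passes square the magnitude response, the design cutoff is
#' widened by `(sqrt(2) - 1)^(-1/(2 * order))` so that the overall response is
#' still -3 dB at `cutoff_hz`.
#'
#' @param x numeric series on a uniform grid; `NA` runs (blinks) are bridged
#'   by linear interpolation before filtering and restored to `NA` after.
#' @param cutoff_hz -3 dB cutoff of the combined forward-backward response.
#' @param fs sampling rate (Hz).
#' @param order Butterworth order of each pass (default 2).
#' @param adjust_cutoff widen the design cutoff to compensate the two passes.
#' @return filtered series, same length.
#' @export
zero_phase_lowpass <- function(x, cutoff_hz, fs, order = 2,
                               adjust_cutoff = TRUE) {
  if (fs <= 2 * cutoff_hz) stop("sampling rate must exceed twice the cutoff")
  if (length(x) < 3 * (order + 1) * 3)
    stop("series too short for stable zero-phase filtering")
  fc <- if (adjust_cutoff) cutoff_hz / (sqrt(2) - 1)^(1 / (2 * order))
        else cutoff_hz
  if (fc >= fs / 2) fc <- 0.99 * fs / 2
  na_mask <- is.na(x)
  if (any(na_mask)) {
    if (all(na_mask)) return(x)
    x <- stats::approx(which(!na_mask), x[!na_mask], xout = seq_along(x),
                       rule = 2)$y
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses the zero-state edge transients of
  # plain forward-backward filtering
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * fs / cutoff_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - pad)])
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(pad + 1):(pad + n)]
  y[na_mask] <- NA_real_
  y
}

#' Trim the initial transient of a trial
#'
#' Removes the first `trim_ms` of every stream of a raw trial trace; the
#' beginning 2 s of each trial are excluded from analysis to avoid the
#' initial transient response.
#'
#' @param trace a `trial_trace`.
#' @param trim_ms initial interval to drop (default 2000 ms).
#' @return the trimmed `trial_trace`.
#' @export
trim_initial <- function(trace, trim_ms = 2000) {
  dur <- max(trace$gaze_t_ms) + 1
  if (trim_ms >= dur) stop("trim_ms (", trim_ms,
                           ") must be shorter than the trial (", dur, " ms)")
  if (trim_ms == 0) return(trace)
  keep_g <- trace$gaze_t_ms >= trim_ms
  keep_h <- trace$hand_t_ms >= trim_ms
  for (f in c("target_t_ms", "target_x_px", "gaze_t_ms", "gaze_x_px",
              "gaze_y_px", "pupil_area_px", "valid"))
    trace[[f]] <- trace[[f]][keep_g]
  for (f in c("hand_t_ms", "hand_x_px", "cursor_x_px"))
    trace[[f]] <- trace[[f]][keep_h]
  trace
}

#' Interpolate the 40 Hz hand streams onto the 1000 Hz gaze grid
#'
#' Linear interpolation, endpoints held, so that hand, cursor, target, and
#' gaze share one time base for cross-correlation analysis.
#'
#' @param x series sampled at `t_from`.
#' @param t_from source time stamps (ms), uniform.
#' @param t_to destination time stamps (ms).
#' @return interpolated series of length `length(t_to)`.
#' @export
upsample_linear <- function(x, t_from, t_to) {
  if (length(t_from) > 2) {
    dt <- diff(t_from)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("source time grid is not uniform")
  }
  stats::approx(t_from, x, xout = t_to, rule = 2)$y
}

#' Savitzky-Golay gaze kinematics with plausibility mask
#'
#' Differentiates the (already low-passed) gaze coordinates with a
#' Savitzky-Golay polynomial filter (order 2, 21-sample window at 1000 Hz by
#' default), combines x and y derivatives into Euclidean speed, converts to
#' degrees via the screen's px/deg constant, and masks physiologically
#' implausible samples: speed above 1000 deg/s, absolute acceleration above
#' 100,000 deg/s^2, or samples within one window of a blink.
#'
#' @param gaze_x_px,gaze_y_px filtered gaze coordinates (px, 1000 Hz grid).
#' @param valid logical validity mask (FALSE during blinks).
#' @param screen a [screen_geometry()].
#' @param fs sampling rate (Hz).
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order.
#' @param max_speed_deg_s,max_accel_deg_s2 plausibility limits.
#' @return list of class `kinematic_series` with `speed_deg_s`,
#'   `accel_deg_s2`, `plausible`.
#' @export
compute_kinematics <- function(gaze_x_px, gaze_y_px = NULL, valid = NULL,
                               screen = screen_geometry(), fs = 1000,
                               sg_window = 21, sg_order = 2,
                               max_speed_deg_s = 1000,
                               max_accel_deg_s2 = 1e5) {
  n <- length(gaze_x_px)
  if (sg_window >= n) stop("Savitzky-Golay window longer than the series")
  if (is.null(gaze_y_px)) gaze_y_px <- numeric(n)
  if (is.null(valid)) valid <- rep(TRUE, n)

  bridge <- function(x) {
    na <- is.na(x)
    if (!any(na)) return(x)
    stats::approx(which(!na), x[!na], xout = seq_len(n), rule = 2)$y
  }
  gx <- bridge(gaze_x_px); gy <- bridge(gaze_y_px)

  vx <- signal::sgolayfilt(gx, p = sg_order, n = sg_window, m = 1) * fs
  vy <- signal::sgolayfilt(gy, p = sg_order, n = sg_window, m = 1) * fs
  ax <- signal::sgolayfilt(gx, p = sg_order, n = sg_window, m = 2) * fs^2
  ay <- signal::sgolayfilt(gy, p = sg_order, n = sg_window, m = 2) * fs^2

  speed <- sqrt(vx^2 + vy^2) / screen$px_per_deg
  accel <- sqrt(ax^2 + ay^2) / screen$px_per_deg

  near_invalid <- if (any(!valid)) {
    half <- (sg_window - 1) %/% 2
    inv <- which(!valid)
    idx <- unique(pmax(1, pmin(n, rep(inv, each = 2 * half + 1) +
                                 rep(-half:half, length(inv)))))
    m <- rep(FALSE, n); m[idx] <- TRUE; m
  } else rep(FALSE, n)

  plausible <- speed <= max_speed_deg_s & accel <= max_accel_deg_s2 &
    !near_invalid
  # derivative estimates in the first/last window are edge-contaminated
  edge <- min(n, sg_window)
  plausible[c(seq_len(edge), (n - edge + 1):n)] <- FALSE
  structure(list(speed_deg_s = speed, accel_deg_s2 = accel,
                 plausible = plausible),
            class = "kinematic_series")
}

#' Preprocess one trial onto the analysis grid
#'
#' Composes the preprocessing stages in protocol order: trim the initial
#' transient, upsample the 40 Hz hand and cursor streams to the 1000 Hz gaze
#' grid, low-pass the hand and cursor at 10 Hz and the gaze at 50 Hz with
#' zero-phase Butterworth filters, and compute Savitzky-Golay kinematics for
#' the saccade detector.
#'
#' @param trace a raw `trial_trace`.
#' @param config a [protocol_config()].
#' @param hand_cutoff_hz,gaze_cutoff_hz filter cutoffs.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return list of class `aligned_trial`: labels, `t_ms`, `target_x_px`,
#'   `hand_x_px`, `cursor_x_px`, `gaze_x_px`, `gaze_y_px`, `pupil_area_px`,
#'   `valid`, `kinematics`, and (when present in the input) `ground_truth`.
#' @export
preprocess_trial <- function(trace, config = protocol_config(),
                             hand_cutoff_hz = 10, gaze_cutoff_hz = 50,
                             sg_window = 21, sg_order = 2) {
  tr <- trim_initial(trace, config$trim_ms)
  fs <- config$gaze_rate_hz
  t_ms <- tr$gaze_t_ms
  hand <- upsample_linear(tr$hand_x_px, tr$hand_t_ms, t_ms)
  cursor <- upsample_linear(tr$cursor_x_px, tr$hand_t_ms, t_ms)
  hand_f <- zero_phase_lowpass(hand, hand_cutoff_hz, fs)
  cursor_f <- zero_phase_lowpass(cursor, hand_cutoff_hz, fs)
  gaze_x_f <- zero_phase_lowpass(tr$gaze_x_px, gaze_cutoff_hz, fs)
  gaze_y_f <- zero_phase_lowpass(tr$gaze_y_px, gaze_cutoff_hz, fs)
  kin <- compute_kinematics(gaze_x_f, gaze_y_f, tr$valid,
                            screen = config$screen, fs = fs,
                            sg_window = sg_window, sg_order = sg_order)
  # ground-truth event times are absolute; keep events whose tail survives
  # the trim (their onset is clamped to the analysis window)
  gt <- tr$ground_truth
  if (!is.null(gt)) {
    gt$pursuit_x_px <- gt$pursuit_x_px[trace$gaze_t_ms >= config$trim_ms]
    if (nrow(gt$true_saccades) > 0) {
      ts <- gt$true_saccades
      keep <- ifelse(is.na(ts$glissade_offset_ms), ts$offset_ms,
                     ts$glissade_offset_ms) > config$trim_ms
      ts <- ts[keep, , drop = FALSE]
      ts$onset_ms <- pmax(ts$onset_ms, config$trim_ms)
      gt$true_saccades <- ts
    }
  }
  structure(list(participant_id = tr$participant_id, group = tr$group,
                 trial_order = tr$trial_order, phase = tr$phase,
                 delay_ms = tr$delay_ms,
                 t_ms = t_ms, target_x_px = tr$target_x_px,
                 hand_x_px = hand_f, cursor_x_px = cursor_f,
                 gaze_x_px = gaze_x_f, gaze_y_px = gaze_y_f,
                 pupil_area_px = tr$pupil_area_px, valid = tr$valid,
                 kinematics = kin, ground_truth = gt),
            class = "aligned_trial")
}
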