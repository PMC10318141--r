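#' Behavioural simulator parameters
#'
#' Parameters of the synthetic participant used to generate hand, cursor,
#' gaze and pupil streams with known ground truth. The simulator is an
#' emulation of the study conditions for testing the analysis pipeline, not a
#' model of human motor learning: within a trial the hand follows the target
#' with a fixed visuomotor delay, band-limited by a low-pass response, plus
#' stationary coloured noise; gaze pursues the target with a signed lead and
#' carries injected saccades, glissades and blinks.
#'
#' In adaptation trials the simulated participant advances the hand by
#' `adapt_advance_ms` to compensate for the 200 ms cursor feedback delay, so
#' the effective target-to-cursor delay there is
#' `hand_delay_ms + feedback_delay - adapt_advance_ms`.
#'
#' @param hand_delay_ms visuomotor response latency of the hand (ms).
#' @param adapt_advance_ms anticipatory advance applied in adaptation trials.
#' @param hand_cutoff_hz low-pass bandwidth of the simulated arm (Hz).
#' @param motor_noise_sd_px stationary SD of the hand noise (px).
#' @param noise_ar coefficient of the AR(1) colouring of the hand noise.
#' @param gaze_lead_ms signed gaze-target lead (positive = gaze ahead).
#' @param gaze_noise_sd_px SD of the smooth pursuit noise (px).
#' @param saccade_rate_hz mean rate of injected saccades (per second).
#' @param saccade_peak_deg_s peak speed of injected saccades (deg/s).
#' @param saccade_dur_ms duration of the saccadic excursion (ms).
#' @param glissade_prob probability that a saccade is followed by a glissade.
#' @param saccade_style `"excursion"` (out-and-back, zero net displacement;
#'   keeps the pursuit trace clean for lag-recovery studies) or `"jump"`
#'   (monophasic with persistent displacement and sign-alternating corrective
#'   placement; the realistic speed-profile shape for detector benchmarks).
#' @param blink_rate_hz mean blink rate (per second).
#' @param blink_dur_ms blink (missing-data) duration (ms).
#' @param pupil_mean_px,pupil_sd_px mean pupil area and sample noise SD (px).
#' @param pupil_drift_px amplitude of the slow pupil drift (px).
#' @return An object of class `simulator_params`.
#' @export
simulator_params <- function(hand_delay_ms = 43, adapt_advance_ms = 197,
                             hand_cutoff_hz = 6, motor_noise_sd_px = 15,
                             noise_ar = 0.85,
                             gaze_lead_ms = 100, gaze_noise_sd_px = 3,
                             saccade_rate_hz = 1.64,
                             saccade_peak_deg_s = 300, saccade_dur_ms = 48,
                             glissade_prob = 0.4,
                             saccade_style = c("excursion", "jump"),
                             blink_rate_hz = 0.1, blink_dur_ms = 150,
                             pupil_mean_px = 850, pupil_sd_px = 8,
                             pupil_drift_px = 20) {
  stopifnot(hand_delay_ms >= 0, hand_cutoff_hz > 0, motor_noise_sd_px >= 0,
            noise_ar >= 0, noise_ar < 1, gaze_noise_sd_px >= 0,
            saccade_rate_hz >= 0, saccade_peak_deg_s >= 0, saccade_dur_ms > 0,
            glissade_prob >= 0, glissade_prob <= 1, blink_rate_hz >= 0,
            pupil_mean_px > 0, pupil_sd_px >= 0)
  saccade_style <- match.arg(saccade_style)
  structure(as.list(environment()), class = "simulator_params")
}

#' Group presets for the behavioural simulator
#'
#' Two parameter sets emulating the qualitative young/older group contrast:
#' baseline hand delays of 43 vs 89 ms, adaptation advances such that
#' adaptation-phase target-cursor lags land near 46 vs 114 ms, gaze leads of
#' 100 vs 60 ms, saccade rates of 1.64 vs 2.23 per second, and motor noise of
#' 15 vs 32 px.
#'
#' @param group `"young"` or `"older"`.
#' @return A [simulator_params()] object.
#' @export
group_preset <- function(group = c("young", "older")) {
  group <- match.arg(group)
  if (group == "young") {
    simulator_params(hand_delay_ms = 43, adapt_advance_ms = 197,
                     motor_noise_sd_px = 15, gaze_lead_ms = 100,
                     saccade_rate_hz = 1.64, pupil_mean_px = 900)
  } else {
    simulator_params(hand_delay_ms = 89, adapt_advance_ms = 175,
                     motor_noise_sd_px = 32, gaze_lead_ms = 60,
                     saccade_rate_hz = 2.23, pupil_mean_px = 700)
  }
}

# Shift a series on its own grid by an integer number of samples, holding the
# boundary value. Positive shift_samples delays the series.
shift_hold <- function(x, shift_samples) {
  n <- length(x)
  s <- as.integer(round(shift_samples))
  if (s == 0) return(x)
  if (abs(s) >= n) stop("shift exceeds series length")
  if (s > 0) c(rep(x[1], s), x[seq_len(n - s)])
  else c(x[(1 - s):n], rep(x[n], -s))
}

#' Simulate the hand trace for one trial
#'
#' The hand follows the target with latency `hand_delay_ms` (reduced by
#' `adapt_advance_ms` when `adapted = TRUE`), low-passed at `hand_cutoff_hz`
#' to emulate limb dynamics, then sampled at the digitizer rate with added
#' stationary AR(1) noise of SD `motor_noise_sd_px`.
#'
#' @param traj a [generate_target_trajectory()] result.
#' @param params a [simulator_params()].
#' @param config a [protocol_config()] (for the sampling rates).
#' @param adapted logical; apply the anticipatory advance of adaptation trials.
#' @return list with `t_ms`, `hand_x_px` (at `hand_rate_hz`) and the noiseless
#'   series `clean_x_px`.
#' @export
simulate_hand <- function(traj, params, config = protocol_config(),
                          adapted = FALSE) {
  fs <- config$gaze_rate_hz
  delay <- params$hand_delay_ms - if (adapted) params$adapt_advance_ms else 0
  if (abs(delay) >= config$tracking_duration_ms)
    stop("hand delay exceeds trial duration")
  shifted <- shift_hold(traj$x_px, delay * fs / 1000)
  clean <- zero_phase_lowpass(shifted, params$hand_cutoff_hz, fs)
  step <- fs / config$hand_rate_hz
  idx <- seq(1, length(clean), by = step)
  clean40 <- clean[idx]
  n40 <- length(clean40)
  noise <- if (params$motor_noise_sd_px > 0) {
    innov_sd <- params$motor_noise_sd_px * sqrt(1 - params$noise_ar^2)
    as.numeric(stats::filter(stats::rnorm(n40, 0, innov_sd),
                             params$noise_ar, method = "recursive"))
  } else numeric(n40)
  list(t_ms = traj$t_ms[idx], hand_x_px = clean40 + noise,
       clean_x_px = clean40)
}

#' Apply the cursor feedback delay
#'
#' The cursor replays the hand trace `delay_ms` later; during the first
#' `delay_ms` the cursor holds the initial hand position. The delay must be an
#' integer number of samples at the series' own rate (200 ms is exactly 8
#' samples at 40 Hz and 200 samples at 1000 Hz).
#'
#' @param hand_x_px hand position series.
#' @param delay_ms feedback delay (ms, >= 0).
#' @param rate_hz sampling rate of the series.
#' @return delayed series of the same length.
#' @export
apply_feedback_delay <- function(hand_x_px, delay_ms, rate_hz = 40) {
  if (delay_ms < 0) stop("feedback delay must be non-negative")
  s <- delay_ms * rate_hz / 1000
  if (abs(s - round(s)) > 1e-9)
    stop("delay_ms must be a multiple of the sampling interval (",
         1000 / rate_hz, " ms)")
  shift_hold(hand_x_px, s)
}

# Place non-overlapping event onsets by thinning a Poisson draw.
place_events <- function(n_target, dur_ms, window_ms, margin_ms = 100) {
  if (n_target == 0) return(numeric(0))
  onsets <- sort(stats::runif(n_target, margin_ms,
                              window_ms - dur_ms - margin_ms))
  keep <- c(TRUE, diff(onsets) > dur_ms + 20)
  onsets[keep]
}

#' Simulate gaze, pupil, and oculomotor ground truth for one trial
#'
#' Pursuit follows the target with a signed lead plus smooth (low-passed)
#' noise. Saccades are injected at Poisson times as transient excursions with
#' a Gaussian position profile, so each lobe of the biphasic velocity is
#' approximately Gaussian and the eye returns to the pursuit locus by event
#' offset; a fraction carries a smaller opposite-signed glissade wobble
#' immediately after. Blinks appear as invalid gaps. Pupil area is a slow
#' sinusoidal drift around `pupil_mean_px` plus white noise.
#'
#' @inheritParams simulate_hand
#' @return list with `t_ms`, `gaze_x_px`, `gaze_y_px`, `pupil_area_px`,
#'   `valid`, and `ground_truth` (list with `true_gt_lag_ms`,
#'   `true_noise_sd_px`, and a data.frame `true_saccades` of `onset_ms`,
#'   `offset_ms`, `peak_deg_s`, `glissade_offset_ms`).
#' @export
simulate_gaze <- function(traj, params, config = protocol_config()) {
  fs <- config$gaze_rate_hz
  n <- length(traj$x_px)
  dur_ms <- config$tracking_duration_ms
  px_deg <- config$screen$px_per_deg

  pursuit <- shift_hold(traj$x_px, -params$gaze_lead_ms * fs / 1000)
  if (params$gaze_noise_sd_px > 0) {
    smooth_noise <- zero_phase_lowpass(stats::rnorm(n), 20, fs)
    smooth_noise <- smooth_noise / stats::sd(smooth_noise) *
      params$gaze_noise_sd_px
    pursuit <- pursuit + smooth_noise
  }

  # blinks first: saccades are never injected inside a lost-signal gap
  blink_onsets <- place_events(
    stats::rpois(1, params$blink_rate_hz * dur_ms / 1000),
    params$blink_dur_ms, dur_ms)

  sac_dur <- params$saccade_dur_ms
  n_sac <- stats::rpois(1, params$saccade_rate_hz * dur_ms / 1000)
  onsets <- place_events(n_sac, sac_dur + 60, dur_ms)
  if (n_sac > 0 && length(onsets) < 0.5 * n_sac)
    stop("saccade rate too high to place non-overlapping events")
  if (length(blink_onsets) > 0 && length(onsets) > 0) {
    clear <- vapply(onsets, function(on)
      all(on + sac_dur + 90 < blink_onsets |
            on > blink_onsets + params$blink_dur_ms + 40), logical(1))
    onsets <- onsets[clear]
  }

  sac_comp <- numeric(n)
  t_ms <- traj$t_ms
  truth <- list()
  # "excursion": x(t) = A/2 (1 - cos(2 pi t / L)) on [0, L] - out-and-back
  # with sinusoidal biphasic velocity (peak A pi / L) and zero net
  # displacement, so the eye rejoins the pursuit locus at event offset.
  # "jump": x(t) = A/2 (1 - cos(pi t / L)) then held - a monophasic saccade
  # with persistent displacement (peak speed A pi / (2 L)); signs alternate
  # toward zero cumulative offset so gaze stays near the pursuit locus.
  raised_cos <- function(amp, on, len, cycles = 1) {
    win <- which(t_ms >= on & t_ms <= on + len)
    list(win = win,
         x = amp / 2 * (1 - cos(cycles * 2 * pi * (t_ms[win] - on) / len)))
  }
  vp_px_ms <- params$saccade_peak_deg_s * px_deg / 1000
  jump <- identical(params$saccade_style, "jump")
  offset_px <- 0
  for (on in onsets) {
    if (jump) {
      amp_px <- vp_px_ms * 2 * sac_dur / pi
      sgn <- if (abs(offset_px) > amp_px / 2) -sign(offset_px)
             else sample(c(-1, 1), 1)
      rc <- raised_cos(sgn * amp_px, on, sac_dur, cycles = 0.5)
      sac_comp[rc$win] <- sac_comp[rc$win] + rc$x
      after <- t_ms > on + sac_dur
      sac_comp[after] <- sac_comp[after] + sgn * amp_px
      offset_px <- offset_px + sgn * amp_px
    } else {
      amp_px <- vp_px_ms * sac_dur / pi
      sgn <- sample(c(-1, 1), 1)
      rc <- raised_cos(sgn * amp_px, on, sac_dur)
      sac_comp[rc$win] <- sac_comp[rc$win] + rc$x
    }
    gli_off <- NA_real_
    if (stats::runif(1) < params$glissade_prob) {
      gli_dur <- 24
      rg <- raised_cos(-sgn * 0.2 * amp_px, on + sac_dur, gli_dur)
      sac_comp[rg$win] <- sac_comp[rg$win] + rg$x
      gli_off <- on + sac_dur + gli_dur
    }
    truth[[length(truth) + 1]] <-
      data.frame(onset_ms = on, offset_ms = on + sac_dur,
                 peak_deg_s = params$saccade_peak_deg_s,
                 glissade_offset_ms = gli_off)
  }
  true_saccades <- if (length(truth)) do.call(rbind, truth) else
    data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
               peak_deg_s = numeric(0), glissade_offset_ms = numeric(0))

  gaze_x <- pursuit + sac_comp
  gaze_y <- if (params$gaze_noise_sd_px > 0) {
    yn <- zero_phase_lowpass(stats::rnorm(n), 20, fs)
    yn / stats::sd(yn) * params$gaze_noise_sd_px
  } else numeric(n)

  valid <- rep(TRUE, n)
  for (on in blink_onsets) {
    bwin <- which(t_ms >= on & t_ms < on + params$blink_dur_ms)
    valid[bwin] <- FALSE
  }
  gaze_x[!valid] <- NA_real_
  gaze_y[!valid] <- NA_real_

  pupil <- params$pupil_mean_px +
    params$pupil_drift_px * sin(2 * pi * 0.01 * t_ms / 1000 +
                                  stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, params$pupil_sd_px)
  pupil[!valid] <- NA_real_

  list(t_ms = t_ms, gaze_x_px = gaze_x, gaze_y_px = gaze_y,
       pupil_area_px = pupil, valid = valid,
       ground_truth = list(true_gt_lag_ms = params$gaze_lead_ms,
                           true_noise_sd_px = params$gaze_noise_sd_px,
                           pursuit_x_px = pursuit,
                           true_saccades = true_saccades))
}

#' Simulate one complete trial
#'
#' @inheritParams simulate_hand
#' @param phase trial phase label (`"baseline"`, `"adaptation"`, `"post"`).
#' @param trial_order 1-based trial position in the session.
#' @param participant_id,group labels carried into the trace.
#' @return A `trial_trace` list: labels plus `target_t_ms`, `target_x_px`
#'   (1000 Hz), `hand_t_ms`, `hand_x_px`, `cursor_x_px` (40 Hz), `gaze_t_ms`,
#'   `gaze_x_px`, `gaze_y_px`, `pupil_area_px`, `valid` (1000 Hz), the applied
#'   `delay_ms`, and `ground_truth`.
#' @export
simulate_trial <- function(config = protocol_config(),
                           params = group_preset("young"),
                           phase = "baseline", trial_order = 1L,
                           participant_id = "sim01", group = "young") {
  traj <- generate_target_trajectory(config)
  delay_ms <- unname(config$delay_ms_by_phase[[phase]])
  adapted <- phase == "adaptation"
  hand <- simulate_hand(traj, params, config, adapted = adapted)
  cursor <- apply_feedback_delay(hand$hand_x_px, delay_ms,
                                 config$hand_rate_hz)
  gaze <- simulate_gaze(traj, params, config)
  gt <- gaze$ground_truth
  gt$true_tc_lag_ms <- delay_ms + params$hand_delay_ms -
    if (adapted) params$adapt_advance_ms else 0
  gt$true_motor_noise_sd_px <- params$motor_noise_sd_px
  structure(list(participant_id = participant_id, group = group,
                 trial_order = as.integer(trial_order), phase = phase,
                 delay_ms = delay_ms,
                 target_t_ms = traj$t_ms, target_x_px = traj$x_px,
                 components = traj$components,
                 hand_t_ms = hand$t_ms, hand_x_px = hand$hand_x_px,
                 cursor_x_px = cursor,
                 gaze_t_ms = gaze$t_ms, gaze_x_px = gaze$gaze_x_px,
                 gaze_y_px = gaze$gaze_y_px,
                 pupil_area_px = gaze$pupil_area_px, valid = gaze$valid,
                 ground_truth = gt),
            class = "trial_trace")
}

#' Simulate a full session
#'
#' Emits trials in protocol order (baseline, adaptation, post) with fresh
#' target phases per trial, correct phase labels, contiguous `trial_order`,
#' and the cursor feedback delay applied only in adaptation trials.
#'
#' @inheritParams simulate_trial
#' @param seed optional integer seed; when given the whole session is
#'   reproducible bit-exactly.
#' @return A list of class `session` of `trial_trace` objects, with
#'   attributes `participant_id`, `group`, `config`, `params`, `seed`.
#' @export
simulate_session <- function(config = protocol_config(),
                             params = group_preset("young"),
                             participant_id = "sim01", group = "young",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phases <- session_phases(config)
  trials <- vector("list", length(phases))
  for (i in seq_along(phases)) {
    trials[[i]] <- simulate_trial(config, params, phase = phases[i],
                                  trial_order = i,
                                  participant_id = participant_id,
                                  group = group)
  }
  structure(trials, class = "session", participant_id = participant_id,
            group = group, config = config, params = params, seed = seed)
}
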