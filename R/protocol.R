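#' Screen geometry and pixel/degree conversion
#'
#' Describes the display used in the tracking task and carries the single
#' pixel-to-visual-angle conversion constant used throughout the package.
#' The default of 30 px per degree follows from the task's stated equivalence
#' of a 387-pixel maximum target shift and 12.9 degrees of visual angle
#' (387 / 12.9 = 30), which keeps degree-valued error metrics consistent with
#' the protocol's own unit conventions.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @param px_per_deg pixels per degree of visual angle.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            viewing_distance_cm = 50, px_per_deg = 30) {
  stopifnot(width_px > 0, height_px > 0, viewing_distance_cm > 0,
            px_per_deg > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 viewing_distance_cm = viewing_distance_cm,
                 px_per_deg = px_per_deg),
            class = "screen_geometry")
}

#' Convert pixels to degrees of visual angle
#' @param px numeric vector in pixels.
#' @param screen a [screen_geometry()].
#' @return numeric vector in degrees.
#' @export
px_to_deg <- function(px, screen = screen_geometry()) px / screen$px_per_deg

#' Sine components of the target trajectory
#'
#' The target moves along the horizontal axis following a sum of five
#' non-harmonic sinusoids. The default frequencies (0.09, 0.165, 0.195,
#' 0.375, 0.495 Hz) and amplitudes (20, 50, 20, 100, 20 px) are the task's
#' published constants; phases are drawn fresh for every trial.
#'
#' @param freq_hz numeric vector of temporal frequencies (Hz).
#' @param amp_px numeric vector of amplitudes (px).
#' @param phase_rad numeric vector of phases in `[0, 2*pi)`, or `NULL` when
#'   phases are to be drawn at generation time.
#' @return A data.frame of class `sine_components`.
#' @export
sine_components <- function(freq_hz = c(0.09, 0.165, 0.195, 0.375, 0.495),
                            amp_px = c(20, 50, 20, 100, 20),
                            phase_rad = NULL) {
  stopifnot(length(freq_hz) == length(amp_px), all(freq_hz > 0),
            all(amp_px >= 0))
  if (!is.null(phase_rad)) {
    stopifnot(length(phase_rad) == length(freq_hz),
              all(phase_rad >= 0), all(phase_rad < 2 * pi))
  }
  structure(data.frame(freq_hz = freq_hz, amp_px = amp_px,
                       phase_rad = if (is.null(phase_rad)) NA_real_ else phase_rad),
            class = c("sine_components", "data.frame"))
}

#' Experimental protocol configuration
#'
#' Session structure and timing of the tracking task: 4 baseline trials with
#' veridical feedback, 12 adaptation trials in which the cursor is delayed by
#' 200 ms relative to the hand, and 3 post-test trials with veridical feedback
#' again. Each tracking period lasts 59,500 ms; the first 2 s of every trial
#' are discarded from analysis to avoid the initial transient.
#'
#' @param n_baseline,n_adapt,n_post trial counts per phase.
#' @param tracking_duration_ms duration of the tracked portion of each trial.
#' @param trim_ms initial interval excluded from analysis.
#' @param delay_ms_by_phase named numeric vector mapping phase to the cursor
#'   feedback delay in ms.
#' @param hand_rate_hz,gaze_rate_hz sampling rates of the digitizer and the
#'   eye tracker.
#' @param components a [sine_components()] object (amplitudes/frequencies;
#'   phases drawn per trial).
#' @param max_shift_px maximum admissible absolute target displacement from
#'   its start position.
#' @param screen a [screen_geometry()].
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_baseline = 4L, n_adapt = 12L, n_post = 3L,
                            tracking_duration_ms = 59500,
                            trim_ms = 2000,
                            delay_ms_by_phase = c(baseline = 0, adaptation = 200,
                                                  post = 0),
                            hand_rate_hz = 40, gaze_rate_hz = 1000,
                            components = sine_components(),
                            max_shift_px = 387,
                            screen = screen_geometry()) {
  stopifnot(n_baseline >= 0, n_adapt >= 0, n_post >= 0,
            trim_ms < tracking_duration_ms,
            all(c("baseline", "adaptation", "post") %in%
                  names(delay_ms_by_phase)),
            hand_rate_hz > 0, gaze_rate_hz > 0, max_shift_px > 0,
            inherits(components, "sine_components"),
            inherits(screen, "screen_geometry"))
  if (gaze_rate_hz %% hand_rate_hz != 0)
    stop("gaze_rate_hz must be an integer multiple of hand_rate_hz")
  structure(list(n_baseline = as.integer(n_baseline),
                 n_adapt = as.integer(n_adapt),
                 n_post = as.integer(n_post),
                 tracking_duration_ms = tracking_duration_ms,
                 trim_ms = trim_ms,
                 delay_ms_by_phase = delay_ms_by_phase,
                 hand_rate_hz = hand_rate_hz,
                 gaze_rate_hz = gaze_rate_hz,
                 components = components,
                 max_shift_px = max_shift_px,
                 screen = screen),
            class = "protocol_config")
}

#' Phase labels of a session in trial order
#' @param config a [protocol_config()].
#' @return character vector of length `n_baseline + n_adapt + n_post`.
#' @export
session_phases <- function(config) {
  rep(c("baseline", "adaptation", "post"),
      c(config$n_baseline, config$n_adapt, config$n_post))
}

# Evaluate the sum-of-sines at times t (seconds), recentred so x(0) = 0.
eval_sines <- function(components, t_s) {
  x <- numeric(length(t_s))
  for (i in seq_len(nrow(components))) {
    x <- x + components$amp_px[i] *
      sin(2 * pi * components$freq_hz[i] * t_s + components$phase_rad[i])
  }
  x - sum(components$amp_px * sin(components$phase_rad))
}

#' Generate a constrained sum-of-sines target trajectory
#'
#' Draws phases uniformly on `[0, 2*pi)` for each sine component, evaluates
#' `x(t) = sum_i A_i sin(2 pi f_i t + phi_i)` on the 1000 Hz time grid,
#' recentres it so that the target starts at the screen centre (`x(0) = 0`),
#' and accepts the draw only if the maximum absolute displacement stays within
#' `max_shift_px` (387 px = 12.9 deg by default). Rejected draws are resampled
#' with fresh phases, up to `max_attempts` times.
#'
#' @param config a [protocol_config()].
#' @param phases optional fixed phases (radians, one per component); when
#'   supplied no rejection sampling takes place but the constraint is still
#'   checked.
#' @param max_attempts bound on rejection resampling.
#' @return A list of class `target_trajectory` with fields `t_ms`, `x_px`, and
#'   `components` (with the accepted phases filled in).
#' @export
generate_target_trajectory <- function(config = protocol_config(),
                                       phases = NULL, max_attempts = 1000L) {
  comps <- config$components
  n <- round(config$tracking_duration_ms * config$gaze_rate_hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / config$gaze_rate_hz
  t_s <- t_ms / 1000
  for (attempt in seq_len(max_attempts)) {
    comps$phase_rad <- if (is.null(phases))
      stats::runif(nrow(comps), 0, 2 * pi) else phases
    x <- eval_sines(comps, t_s)
    if (max(abs(x)) <= config$max_shift_px) {
      return(structure(list(t_ms = t_ms, x_px = x, components = comps),
                       class = "target_trajectory"))
    }
    if (!is.null(phases))
      stop("fixed phases violate the maximum-shift constraint (",
           round(max(abs(x)), 1), " px > ", config$max_shift_px, " px)")
  }
  stop("no trajectory satisfying max |x - x(0)| <= ", config$max_shift_px,
       " px found in ", max_attempts, " attempts")
}

#' Amplitude spectrum of a uniformly sampled series
#'
#' Hann-windowed, zero-padded discrete amplitude spectrum, normalised so that
#' a pure sinusoid well inside the band reads out its amplitude. Used to
#' verify the spectral content of generated trajectories.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param pad_factor zero-padding factor for finer frequency interpolation.
#' @return data.frame with columns `freq_hz` and `amplitude`.
#' @export
amplitude_spectrum <- function(x, fs, pad_factor = 8) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(n * pad_factor))
  sp <- abs(stats::fft(c(xw, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  # Hann window coherent gain = mean(w) = 0.5; one-sided amplitude scaling
  amp <- 2 * sp / (n * mean(w))
  data.frame(freq_hz = (seq_len(nfft %/% 2) - 1) * fs / nfft, amplitude = amp)
}

#' Spectral peaks above a relative floor
#'
#' Local maxima of an amplitude spectrum exceeding `rel_floor` times the
#' global maximum.
#'
#' @param spectrum output of [amplitude_spectrum()].
#' @param rel_floor relative amplitude floor (default 1%).
#' @return data.frame of peak `freq_hz` and `amplitude`, ordered by frequency.
#' @export
spectral_peaks <- function(spectrum, rel_floor = 0.01) {
  a <- spectrum$amplitude
  n <- length(a)
  is_peak <- c(FALSE, a[2:(n - 1)] > a[1:(n - 2)] &
                 a[2:(n - 1)] >= a[3:n], FALSE)
  keep <- is_peak & a > rel_floor * max(a)
  data.frame(freq_hz = spectrum$freq_hz[keep], amplitude = a[keep])
}

#' Least-squares refit of sinusoid amplitudes at known frequencies
#'
#' Regresses a series on sine/cosine pairs at the supplied frequencies (plus
#' an intercept absorbing the recentring offset) and returns the implied
#' amplitude of each component. On a noise-free generated trajectory this
#' recovers the configured amplitudes essentially exactly.
#'
#' @param x series on a uniform grid.
#' @param fs sampling rate (Hz).
#' @param freq_hz component frequencies.
#' @return numeric vector of fitted amplitudes (px), one per frequency.
#' @export
refit_amplitudes <- function(x, fs, freq_hz) {
  t_s <- (seq_along(x) - 1) / fs
  X <- do.call(cbind, lapply(freq_hz, function(f)
    cbind(sin(2 * pi * f * t_s), cos(2 * pi * f * t_s))))
  fit <- stats::lsfit(X, x)
  b <- fit$coefficients[-1]
  sqrt(b[seq(1, length(b), 2)]^2 + b[seq(2, length(b), 2)]^2)
}
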