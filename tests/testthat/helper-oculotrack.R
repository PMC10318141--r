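# Shared fixtures: reduced-duration protocol for fast structural tests
# (20 s tracked, 2 s trimmed); the full 59.5 s protocol is used where the
# statistics of the adaptive detector require the full-length speed sample.

fast_config <- function(duration_ms = 20000, ...) {
  protocol_config(tracking_duration_ms = duration_ms, ...)
}

# deterministic participant: no saccades, no blinks, no noise (overridable)
quiet_params <- function(...) {
  base <- list(motor_noise_sd_px = 0, gaze_noise_sd_px = 0,
               saccade_rate_hz = 0, blink_rate_hz = 0,
               pupil_sd_px = 0, pupil_drift_px = 0)
  do.call(simulator_params, utils::modifyList(base, list(...)))
}

# direct closed-form evaluation of the recentred sum of sines (independent
# oracle for the trajectory generator)
oracle_sum_of_sines <- function(freq, amp, phase, t_s) {
  x <- rep(0, length(t_s))
  for (i in seq_along(freq))
    x <- x + amp[i] * sin(2 * pi * freq[i] * t_s + phase[i])
  x - sum(amp * sin(phase))
}
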