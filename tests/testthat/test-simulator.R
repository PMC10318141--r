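test_that("noiseless, delay-free hand reproduces the target at 40 Hz", {
  set.seed(31)
  cfg <- fast_config()
  p <- quiet_params(hand_delay_ms = 0, hand_cutoff_hz = 15)
  traj <- generate_target_trajectory(cfg)
  h <- simulate_hand(traj, p, cfg)
  target40 <- traj$x_px[match(h$t_ms, traj$t_ms)]
  expect_lt(max(abs(h$hand_x_px - target40)), 1)
})

test_that("hand visuomotor delay is recovered by cross-correlation", {
  set.seed(32)
  cfg <- fast_config()
  p <- quiet_params(hand_delay_ms = 120)
  traj <- generate_target_trajectory(cfg)
  h <- simulate_hand(traj, p, cfg)
  h1k <- upsample_linear(h$hand_x_px, h$t_ms, traj$t_ms)
  expect_equal(xcorr_lag(traj$x_px, h1k, max_lag_ms = 500), 120)
})

test_that("motor noise has the configured stationary SD", {
  set.seed(33)
  cfg <- protocol_config()   # full-length trial for a stable SD estimate
  p <- quiet_params(motor_noise_sd_px = 5)
  traj <- generate_target_trajectory(cfg)
  h <- simulate_hand(traj, p, cfg)
  expect_equal(sd(h$hand_x_px - h$clean_x_px), 5, tolerance = 0.1)
})

test_that("feedback delay shifts samples exactly and holds the start", {
  x <- sin(seq(0, 4 * pi, length.out = 400))
  expect_identical(apply_feedback_delay(x, 0, 40), x)
  d <- apply_feedback_delay(x, 200, 40)       # 8 samples at 40 Hz
  expect_identical(d[9:400], x[1:392])
  expect_true(all(d[1:8] == x[1]))
  expect_error(apply_feedback_delay(x, -10, 40), "non-negative")
  expect_error(apply_feedback_delay(x, 13, 40), "multiple")
})

test_that("delay round-trip is exact at 1 ms over the delay grid", {
  set.seed(34)
  cfg <- fast_config()
  p <- quiet_params(hand_delay_ms = 0, motor_noise_sd_px = 2)
  traj <- generate_target_trajectory(cfg)
  h <- simulate_hand(traj, p, cfg)
  h1k <- upsample_linear(h$hand_x_px, h$t_ms, traj$t_ms)
  for (d in c(10, 50, 100, 200, 500)) {
    cur <- apply_feedback_delay(h1k, d, 1000)
    expect_equal(xcorr_lag(h1k, cur, max_lag_ms = 600), d)
  }
})

test_that("noise-free gaze with zero lead reproduces the target", {
  set.seed(35)
  cfg <- fast_config()
  p <- quiet_params(gaze_lead_ms = 0)
  traj <- generate_target_trajectory(cfg)
  g <- simulate_gaze(traj, p, cfg)
  expect_equal(g$gaze_x_px, traj$x_px, tolerance = 1e-12)
  expect_true(all(g$valid))
})

test_that("configured gaze lead appears as a positive gaze-target lag", {
  set.seed(36)
  cfg <- fast_config()
  p <- quiet_params(gaze_lead_ms = 100)
  traj <- generate_target_trajectory(cfg)
  g <- simulate_gaze(traj, p, cfg)
  # positive = follower (target) trails the reference (gaze)
  expect_equal(xcorr_lag(g$gaze_x_px, traj$x_px, max_lag_ms = 500), 100)
})

test_that("injected saccade count is Poisson-consistent with the rate", {
  set.seed(37)
  cfg <- protocol_config()
  p <- quiet_params(saccade_rate_hz = 2)
  traj <- generate_target_trajectory(cfg)
  g <- simulate_gaze(traj, p, cfg)
  lambda <- 2 * cfg$tracking_duration_ms / 1000
  ci <- qpois(c(0.005, 0.995), lambda)
  n <- nrow(g$ground_truth$true_saccades)
  expect_gte(n, ci[1] * 0.9)   # a few draws are thinned for overlap
  expect_lte(n, ci[2])
})

test_that("session builder emits the 4/12/3 protocol structure", {
  set.seed(38)
  cfg <- fast_config(duration_ms = 6000)
  ses <- simulate_session(cfg, quiet_params(), seed = 101)
  expect_length(ses, 19)
  expect_identical(vapply(ses, function(t) t$trial_order, integer(1)), 1:19)
  phases <- vapply(ses, function(t) t$phase, character(1))
  expect_identical(phases, rep(c("baseline", "adaptation", "post"),
                               c(4, 12, 3)))
  delays <- vapply(ses, function(t) t$delay_ms, numeric(1))
  expect_identical(which(delays == 200), 5:16)
  expect_true(all(delays[c(1:4, 17:19)] == 0))
})

test_that("degenerate protocol with no adaptation trials still builds", {
  set.seed(39)
  cfg <- fast_config(duration_ms = 6000, n_adapt = 0)
  ses <- simulate_session(cfg, quiet_params(), seed = 1)
  expect_length(ses, 7)
  expect_true(all(vapply(ses, function(t) t$delay_ms, numeric(1)) == 0))
})

test_that("sessions are bit-identical under a fixed seed", {
  cfg <- fast_config(duration_ms = 6000)
  p <- group_preset("young")
  s1 <- simulate_session(cfg, p, seed = 77)
  s2 <- simulate_session(cfg, p, seed = 77)
  expect_identical(s1[[3]]$hand_x_px, s2[[3]]$hand_x_px)
  expect_identical(s1[[7]]$gaze_x_px, s2[[7]]$gaze_x_px)
  expect_identical(s1[[7]]$pupil_area_px, s2[[7]]$pupil_area_px)
})
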