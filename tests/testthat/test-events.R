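fake_kin <- function(speed) {
  structure(list(speed_deg_s = speed, accel_deg_s2 = numeric(length(speed)),
                 plausible = rep(TRUE, length(speed))),
            class = "kinematic_series")
}

# independent re-implementation of the threshold iteration (oracle)
oracle_threshold <- function(v, init = 200, k = 6, tol = 1) {
  pt <- init
  repeat {
    sub <- v[v < pt]
    if (length(sub) == 0) return(pt)
    new_pt <- mean(sub) + k * sd(sub)
    if (abs(new_pt - pt) < tol) return(new_pt)
    pt <- new_pt
  }
}

test_that("threshold iteration matches an independent oracle exactly", {
  set.seed(51)
  v <- abs(rnorm(57500, 20, 5))
  est <- estimate_peak_threshold(fake_kin(v))
  expect_equal(est$threshold_deg_s, oracle_threshold(v), tolerance = 1e-12)
  expect_gt(est$n_iterations, 1)
})

test_that("constant-speed trace converges via the empty-set rule", {
  v <- rep(20, 5000)
  est <- estimate_peak_threshold(fake_kin(v))
  # first update: mean 20, SD 0 -> threshold 20; sub-threshold set empty
  expect_equal(est$threshold_deg_s, 20)
})

test_that("saturated traces raise an informative error", {
  expect_error(estimate_peak_threshold(fake_kin(rep(500, 100))), "saturated")
})

test_that("threshold lands strictly between pursuit and saccade speeds", {
  set.seed(52)
  cfg <- protocol_config()
  p <- quiet_params(saccade_rate_hz = 2, gaze_noise_sd_px = 3,
                    saccade_peak_deg_s = 300)
  tr <- simulate_trial(cfg, p)
  al <- preprocess_trial(tr, cfg)
  est <- estimate_peak_threshold(al$kinematics)
  expect_gt(est$threshold_deg_s, 30)    # above any pursuit speed
  expect_lt(est$threshold_deg_s, 300)   # below the saccade peaks
})

test_that("a single injected saccade is found with accurate timing", {
  set.seed(53)
  cfg <- protocol_config(tracking_duration_ms = 20000)
  p <- quiet_params(saccade_rate_hz = 0.1, gaze_noise_sd_px = 3,
                    glissade_prob = 0)
  # retry until exactly one event survives placement
  repeat {
    tr <- simulate_trial(cfg, p)
    if (nrow(tr$ground_truth$true_saccades) == 1 &&
        tr$ground_truth$true_saccades$onset_ms[1] > 2500) break
  }
  al <- preprocess_trial(tr, cfg)
  ev <- detect_events(al)
  truth <- al$ground_truth$true_saccades
  expect_equal(nrow(ev$saccades), 1)
  expect_lt(abs(ev$saccades$onset_ms - truth$onset_ms), 8)
  expect_lt(abs(ev$saccades$offset_ms - truth$offset_ms), 8)
})

test_that("traces without peaks yield an empty event set", {
  set.seed(54)
  cfg <- fast_config()
  tr <- simulate_trial(cfg, quiet_params(gaze_noise_sd_px = 2))
  al <- preprocess_trial(tr, cfg)
  ev <- detect_events(al)
  expect_equal(nrow(ev$saccades), 0)
})

test_that("detector recovers injected saccades with high recall/precision", {
  set.seed(55)
  cfg <- protocol_config()
  p <- quiet_params(saccade_rate_hz = 2, gaze_noise_sd_px = 3)
  tr <- simulate_trial(cfg, p)
  al <- preprocess_trial(tr, cfg)
  ev <- detect_events(al)
  m <- match_events(al$ground_truth$true_saccades, ev)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detection is invariant to a constant gaze offset", {
  set.seed(56)
  cfg <- fast_config()
  p <- quiet_params(saccade_rate_hz = 1.5, gaze_noise_sd_px = 3)
  tr <- simulate_trial(cfg, p)
  al1 <- preprocess_trial(tr, cfg)
  tr$gaze_x_px <- tr$gaze_x_px + 500
  al2 <- preprocess_trial(tr, cfg)
  e1 <- detect_events(al1)
  e2 <- detect_events(al2)
  expect_equal(e1$saccades$onset_ms, e2$saccades$onset_ms)
  expect_equal(e1$final_threshold_deg_s, e2$final_threshold_deg_s,
               tolerance = 1e-9)
})

test_that("glissades are attached to saccades and bounded by the window", {
  set.seed(57)
  cfg <- protocol_config()
  p <- quiet_params(saccade_rate_hz = 1.5, gaze_noise_sd_px = 3,
                    glissade_prob = 1)
  tr <- simulate_trial(cfg, p)
  al <- preprocess_trial(tr, cfg)
  ev <- detect_events(al)
  got <- !is.na(ev$saccades$glissade_offset_ms)
  expect_gte(mean(got), 0.9)
  expect_true(all(ev$saccades$glissade_offset_ms[got] -
                    ev$saccades$offset_ms[got] <= 40))
  expect_true(all(ev$saccades$glissade_offset_ms[got] >=
                    ev$saccades$offset_ms[got]))
})

test_that("excise-and-fill interpolates linearly and only inside events", {
  t_ms <- 0:999
  ramp <- 0.3 * t_ms
  no_events <- structure(list(
    saccades = data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                          peak_speed_deg_s = numeric(0),
                          glissade_offset_ms = numeric(0)),
    missing_intervals = data.frame(start_ms = numeric(0),
                                   end_ms = numeric(0))),
    class = "event_set")
  expect_identical(excise_and_fill(ramp, no_events, t_ms), ramp)
  one <- no_events
  one$saccades <- data.frame(onset_ms = 300, offset_ms = 350,
                             peak_speed_deg_s = 200,
                             glissade_offset_ms = NA_real_)
  bumpy <- ramp; bumpy[301:351] <- bumpy[301:351] + 50
  filled <- excise_and_fill(bumpy, one, t_ms)
  # affine signals are reproduced exactly inside the excised span
  expect_equal(filled[301:351], ramp[301:351], tolerance = 1e-9)
  expect_identical(filled[-(301:351)], bumpy[-(301:351)])
})

test_that("filled pursuit stays close to the ground-truth pursuit", {
  set.seed(58)
  cfg <- protocol_config()
  p <- quiet_params(saccade_rate_hz = 2, gaze_noise_sd_px = 3,
                    blink_rate_hz = 0.1)
  tr <- simulate_trial(cfg, p)
  al <- preprocess_trial(tr, cfg)
  ev <- detect_events(al)
  pursuit <- excise_and_fill(al$gaze_x_px, ev, al$t_ms)
  expect_false(anyNA(pursuit))
  rms <- sqrt(mean((pursuit - al$ground_truth$pursuit_x_px)^2))
  expect_lt(rms, 1.5 * p$gaze_noise_sd_px)
})

test_that("saccade rate and mean pupil follow their definitions", {
  ev <- structure(list(
    saccades = data.frame(onset_ms = seq_len(116) * 490,
                          offset_ms = seq_len(116) * 490 + 40,
                          peak_speed_deg_s = 300,
                          glissade_offset_ms = c(rep(NA_real_, 100),
                                                 seq_len(16) * 490 + 60)),
    missing_intervals = data.frame(start_ms = numeric(0),
                                   end_ms = numeric(0))),
    class = "event_set")
  expect_equal(saccade_rate(ev, 58), 2)
  expect_equal(saccade_rate(ev, 58, include_glissades = TRUE),
               (116 + 16) / 58)
  expect_error(saccade_rate(ev, 0), "positive")
  expect_equal(mean_pupil(rep(800, 100)), 800)
  expect_equal(mean_pupil(c(rep(700, 50), rep(900, 50))), 800)
  expect_warning(p <- mean_pupil(c(1, 2), valid = c(FALSE, FALSE)),
                 "no valid")
  expect_true(is.na(p))
})
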