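Package: oculotrack
Title: Eye-Hand Coordination Analysis for Manual Tracking with Delayed Visual
    Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of continuous manual-tracking experiments
    with delayed cursor feedback. Generates protocol-faithful sessions
    (sum-of-five-sines target at 1000 Hz, 40 Hz hand recordings, gaze and pupil
    streams with saccades, glissades and blinks), preprocesses the raw streams
    (trimming, interpolation to a common 1000 Hz grid, zero-phase Butterworth
    filtering, Savitzky-Golay kinematics), detects saccades and glissades with
    an adaptive peak-velocity-threshold algorithm, computes per-trial eye-hand
    coordination metrics (tracking RMSE, cross-correlation lags between target,
    cursor and gaze, lag-corrected random error, saccade rate, mean pupil
    area), and fits group-level linear mixed models relating target-cursor lag
    to gaze-target lag and random error, with likelihood-ratio model
    comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
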