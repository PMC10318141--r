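---
title: "Methods: simulating and analysing delayed-feedback manual tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing delayed-feedback manual tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculotrack)
```

## The task and what the pipeline measures

A participant tracks a horizontally moving target with a cursor driven by a
digitizer while one eye is recorded at 1000 Hz. The target path is a sum of
five non-harmonic sines (0.09, 0.165, 0.195, 0.375, 0.495 Hz; 20, 50, 20,
100, 20 px) with per-trial random phases, recentred to start at the screen
centre and constrained to a maximum excursion of 387 px (12.9° at the
package's 30 px/° conversion). Sessions consist of 4 baseline trials, 12
adaptation trials with the cursor delayed 200 ms relative to the hand, and 3
post-test trials; every tracking period lasts 59.5 s and the first 2 s are
discarded as the initial transient.

Three per-trial quantities carry the scientific content:

* **`TC_lag`** — the cross-correlation lag of the cursor behind the target.
  Under delayed feedback it measures how much of the 200 ms perturbation the
  participant has *not* compensated, i.e. the state of visuomotor adaptation.
* **`GT_lag`** — the lag of the gaze ahead of the target (computed on the
  saccade-excised pursuit trace). A positive lead indexes motor anticipation:
  the oculomotor system predicts the target's future course.
* **`RE`** — the target–cursor RMSE after realigning the cursor by the
  estimated `TC_lag`. With the systematic delay removed, what remains is the
  random error of motor execution.

The group-level question — does anticipation, execution noise, or both drive
individual differences in adaptation — is posed as a set of linear mixed
models for `TC_lag` compared by likelihood ratio.

## Pixel/degree conversion

All error metrics are reported in degrees of visual angle using a fixed
30 px/° constant, derived from the task's own stated equivalence
387 px = 12.9°. The purely geometric conversion from screen size and a 50 cm
viewing distance gives ≈28 px/°; we use the task-consistent value so that
degree-valued results line up with the protocol's definitions. It is a field
of `screen_geometry()` and can be changed.

## The behavioural simulator

The simulator emulates the study conditions so that every stage has testable
ground truth; it is not a model of human motor learning.

* **Hand.** The hand replays the target with a visuomotor latency
  (`hand_delay_ms`), low-passed at `hand_cutoff_hz` (6 Hz) to emulate limb
  dynamics, sampled at 40 Hz, plus stationary AR(1) noise
  (`motor_noise_sd_px`, lag-1 coefficient 0.85 — motor output noise is
  strongly autocorrelated, and white noise would be implausibly easy for the
  lag estimator). In adaptation trials the simulated participant advances the
  hand by `adapt_advance_ms`, so the effective target→cursor delay is
  `hand_delay + 200 − advance`.
* **Group presets.** `group_preset("young")` uses hand delay 43 ms, advance
  197 ms, gaze lead 100 ms, saccade rate 1.64 /s, motor noise 15 px;
  `group_preset("older")` uses 89 ms, 175 ms, 60 ms, 2.23 /s, 32 px. The
  delays and saccade rates are the reported group-level values of the study
  population; leads and noise levels are chosen so that the qualitative group
  contrast (larger adaptation-phase lag and random error for the older
  preset) is reproduced. Within-session learning dynamics are deliberately
  not modelled.
* **Gaze.** Pursuit is the target shifted by the signed lead plus smooth
  (20 Hz low-passed) positional noise. Saccades arrive at Poisson times,
  thinned so events never overlap each other or blinks. Two waveforms are
  available:
  * `"excursion"` (default): a raised-cosine out-and-back bump — the eye
    leaves and rejoins the pursuit locus within the event, giving a biphasic
    sinusoidal velocity profile with a configurable peak. Because the net
    displacement is zero, the excised-and-filled trace can be compared
    directly against the ground-truth pursuit, and lag recovery fixtures
    stay clean.
  * `"jump"`: a monophasic raised-cosine step with persistent displacement,
    signs alternating toward zero cumulative offset. This is the realistic
    single-peaked saccade profile and is the right choice for detector
    benchmarks (see the bistability note below).
  Glissades are smaller (20% amplitude, 24 ms) opposite-signed wobbles
  appended to a configurable fraction of saccades. Blinks are validity gaps,
  never zero-filled. Pupil area is a slow sinusoidal drift around the preset
  mean plus white noise.

## Preprocessing choices

* **Zero-phase filtering.** Butterworth low-passes are applied
  forward–backward. Any phase lag would bias the cross-correlation lags that
  are the primary outcome, so zero-phase filtering is non-negotiable here.
  Two passes square the magnitude response, so the design cutoff is widened
  by `(sqrt(2)−1)^(−1/(2·order))` to keep −3 dB at the nominal cutoff (10 Hz
  hand, 50 Hz gaze, order 2). Plain forward–backward filtering with zero
  initial conditions leaves large edge transients; we pad with an odd
  reflection of the series before filtering and strip it after.
* **Interpolation.** Hand and cursor are linearly interpolated from 40 Hz
  onto the 1000 Hz gaze grid (endpoints held). Linear interpolation is exact
  for the band of interest at this oversampling and keeps 40 Hz samples as
  fixed points.
* **Kinematics.** Velocity and acceleration come from Savitzky–Golay
  differentiation (polynomial order 2, window 21 samples = 21 ms). The window
  is long enough to suppress sample noise yet shorter than a saccadic
  velocity lobe, so peaks survive. Samples with speed above 1000 °/s,
  acceleration above 10⁵ °/s², within one window of a blink, or inside the
  first/last window of the trace (edge-contaminated derivatives) are marked
  implausible and excluded from threshold estimation; implausible runs are
  excised and interpolated like detected events.

## The adaptive detector and a note on its fixed points

The peak-detection threshold is estimated per trial: starting at 200 °/s,
update to `mean + 6·SD` of all plausible samples slower than the current
threshold, until successive thresholds differ by less than 1 °/s. If an
update empties the sub-threshold set (degenerate constant-speed input) the
last threshold is returned. Saccade onsets are found by searching backward
from each supra-threshold peak for the first sample below the global noise
criterion (`mean + 3·SD` of the converged sub-threshold samples) where the
speed is locally rising toward the peak over a 5-sample run; offsets forward
for the first sample below a weighted criterion (0.7 × onset criterion +
0.3 × a locally adaptive factor, `mean + 3·SD` over the 40 ms before onset)
with a 5-sample monotone decay behind it. Events closer than 20 ms are
merged; events shorter than 10 ms are dropped. Glissades extend a saccade
when the speed re-exceeds its offset criterion within 40 ms of the offset,
ending after the last local peak's monotone rise, capped at the window. The
weights, windows and run lengths are not fixed by the published description;
the values above follow the original adaptive-threshold algorithm's practice
for 1000 Hz data and are all configurable.

The update map `PT → mean + 6·SD` has more than one fixed point. When a
large fraction of samples sits in the 30–200 °/s band — which happens with
biphasic out-and-back waveforms at high event rates, because every event
crosses the band four times — the iteration started at 200 °/s can converge
onto a saccade-contaminated upper fixed point (~280 °/s) instead of the
noise-driven one (~50 °/s), and detection then fails. With realistic
monophasic profiles at the same event count the iteration lands on the noise
fixed point on every run. This is a property of the algorithm worth knowing
when interpreting per-trial thresholds: `estimate_peak_threshold()` reports
`n_iterations`, and an unusually high converged threshold on real data is a
diagnostic for a saccade-dense or noisy trial, not a detector bug.

## Coordination metrics

`xcorr_lag()` scans integer-sample shifts in ±1000 ms and returns the shift
maximising the per-window Pearson correlation (means and variances recomputed
on the overlapping window at every shift; ties broken toward zero). The
search window comfortably covers human and imposed lags, whose largest
plausible value here is ≈300 ms. The implementation computes all cross sums
at once via FFT with zero-padded cumulative sums for the window statistics;
it is exact (the test suite checks it against a direct per-shift correlation
loop). Sign conventions are fixed in one place: positive `TC_lag` = cursor
behind target; positive `GT_lag`/`GC_lag` = gaze ahead.

`random_error()` realigns the cursor by the estimated `TC_lag` (not by an
RMSE-minimising search — the realignment is defined by the lag estimate) and
reports the residual RMSE on the overlapping window. Gaze lags are computed
on the excised-and-filled pursuit trace so that saccadic excursions do not
contaminate the pursuit comparison.

## Group statistics

Trials bin into baseline (1–4), adapt1 (5–8), adapt2 (9–12), adapt3 (13–16),
post (17–19). Phase summaries average within participant first and report the
between-participant standard error. Centralization subtracts each
participant's own mean, isolating within-participant covariation; it is
idempotent and removes any participant-constant confound.

The candidate models for `TC_lag` share trial order (TO) as a learning-trend
control and differ in whether age, `GT_lag`, and/or `RE` enter as fixed
effects. Fits are maximum likelihood (models differing in fixed effects are
compared by likelihood ratio, which REML would invalidate). The random
structure is per-participant correlated intercept + TO slope (3 covariance
parameters), which together with 3 fixed effects and the residual gives the
7-parameter count of the baseline model; the full model adds a correlated
random `GT_lag` slope (6 covariance parameters, 11 total). Printed parameter
counts cannot uniquely identify a random structure, so the structure is
configurable per spec in `lag_model_specs()` and the accounting above is the
package's documented choice. Age enters the mixed models in years; group
membership is used for phase summaries. Singular fits are flagged with a
warning but returned, since boundary variance estimates are routine in the
smaller models.

`simulate_cohort_metrics()` generates metrics tables directly from this
generative structure (29 + 23 participants, 12 adaptation trials each, by
default) for power and type-I-error studies of the likelihood-ratio test;
`lrt_rejection_rate()` wraps the replicate loop. Under the null (`b_gt = 0`)
the LRT's rejection rate at α = 0.05 is checked to sit in [0.03, 0.08] over
500 replicates; with the anticipation effect present the same test rejects
essentially always at study-scale n.

## What the synthetic data do and do not establish

The simulator reproduces the protocol's structure, sampling rates, timing,
spectral content and event statistics, with known ground truth, so passing
tests establish that the pipeline recovers what it is supposed to recover —
delays exactly at 1 ms resolution, gaze leads within ±2 ms, injected noise
SDs within 10%, saccades with recall/precision above 0.95 at 10:1 SNR. They
do not establish anything about human data: real pursuit contains gain
changes, anticipatory reversals, drift and tracker artifacts that the
generator deliberately omits, and the behavioural presets hard-code the group
contrast rather than produce it from a learning mechanism. Real recordings
enter through the documented trace schema (`read_session()`), after external
conversion from raw tracker formats.

## Numerical and scale choices

Times are integer milliseconds from tracking onset; positions are pixels in
all files, converted to degrees only in derived metrics. The structural unit
tests run on shortened 6–20 s trials where only arithmetic and bookkeeping
are at stake; detector and metric recovery tests use full-length 59.5 s
trials because the threshold iteration's stability is a large-sample
property. The heaviest checks (1000 trajectory generations; 500-replicate
null calibration of the LRT) run in a few minutes in total. Degenerate
inputs are handled explicitly: constant traces converge through the
empty-set rule, zero-variance series are rejected by the lag estimator,
all-invalid pupil trials yield `NA` with a warning, and events touching the
series edge fall back to boundary-value holds.
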