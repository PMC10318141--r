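# oculotrack

Eye–hand coordination analysis for continuous manual tracking with delayed
visual feedback.

In the underlying paradigm, a participant moves a digitizer to keep a cursor
on a target that drifts horizontally along an unpredictable sum of five
non-harmonic sines (0.09, 0.165, 0.195, 0.375, 0.495 Hz; amplitudes 20, 50,
20, 100, 20 px; maximum excursion 387 px = 12.9° of visual angle). A session
has 4 baseline trials, 12 adaptation trials in which the cursor replays the
hand 200 ms late, and 3 post-test trials; each tracking period lasts 59.5 s.
Hand position is sampled at 40 Hz, gaze (one eye) and pupil area at 1000 Hz.
How well people *anticipate* the target (their gaze runs ahead of it) and how
*noisily* they execute the movement jointly determine how well they adapt to
the feedback delay — dissociating those two contributions is what this
analysis chain is for.

The package implements the full chain:

- **Simulation** — protocol-faithful sessions with a behavioural model
  (visuomotor hand delay, anticipatory advance under adaptation, band-limited
  arm dynamics, coloured motor noise, pursuit gaze with a signed lead,
  injected saccades/glissades/blinks, pupil drift) and complete ground truth,
  so every downstream stage is testable without human data.
- **Preprocessing** — 2 s initial-transient trimming, linear 40→1000 Hz
  interpolation, zero-phase Butterworth low-passes (hand 10 Hz; gaze 50 Hz,
  order 2), Savitzky–Golay velocity/acceleration (order 2, 21 ms window) with
  a physiological plausibility mask (speed ≤ 1000 °/s, |accel| ≤ 10⁵ °/s²).
- **Oculomotor events** — the adaptive peak-velocity-threshold saccade
  detector: iterate *PT ← mean + 6·SD* of sub-threshold speed samples from a
  200 °/s start until the change is below 1 °/s; onsets/offsets by
  backward/forward search against mean + 3·SD noise criteria; glissade
  extension; excision of events with linear-interpolation fill to obtain the
  pursuit-only trace.
- **Coordination metrics** — per trial: target–cursor RMSE (deg),
  cross-correlation lags (target–cursor `TC_lag`, gaze–cursor, gaze–target
  `GT_lag`; ±1000 ms search at 1 ms resolution; positive `TC_lag` = cursor
  behind target, positive `GT_lag` = gaze ahead of target), lag-corrected
  random error `RE` (RMSE after realigning the cursor by the estimated lag),
  saccade rate, mean pupil area.
- **Group statistics** — phase bins (baseline / adapt1–3 / post),
  between-participant phase summaries, within-participant centralization,
  groupwise Pearson correlations, and the six-model linear mixed-model
  comparison `TC_lag ~ {age, TO, GT_lag, RE}` with per-participant random
  intercept + trial-order slope (ML fits; likelihood-ratio tests, AIC/BIC).

## Worked example

```r
library(oculotrack)

cfg <- protocol_config()                       # 4/12/3 trials, 200 ms delay
ses <- simulate_session(cfg, group_preset("older"),
                        participant_id = "older01", group = "older",
                        seed = 42)
out <- run_pipeline(ses, cfg)

head(out$metrics[, c("trial_order", "phase", "bin", "rmse_deg", "tc_lag_ms",
                     "gt_lag_ms", "random_error_deg", "saccade_rate_hz")], 6)
#>   trial_order      phase      bin rmse_deg tc_lag_ms gt_lag_ms random_error_deg
#> 1           1   baseline baseline     1.20        85        60            1.094
#> 2           2   baseline baseline     1.20        91        60            1.070
#> 3           3   baseline baseline     1.11        76        60            1.011
#> 4           4   baseline baseline     1.14        79        60            1.037
#> 5           5 adaptation   adapt1     1.26       132        60            0.994
#> 6           6 adaptation   adapt1     1.18       105        60            1.001
#>   saccade_rate_hz
#> 1            1.67
#> ...

out$summaries$tc_lag
#>   group      bin  mean se n se_defined
#> 1 older baseline  82.8  0 1      FALSE
#> 2 older   adapt1 112.0  0 1      FALSE
#> 3 older   adapt2 113.0  0 1      FALSE
#> 4 older   adapt3 108.8  0 1      FALSE
#> 5 older     post  98.3  0 1      FALSE
```

The target–cursor lag sits near the simulated participant's 89 ms visuomotor
delay at baseline, jumps under the 200 ms feedback delay to the residual
(delay minus anticipatory advance) level around 110 ms, and returns toward
baseline at post-test. The gaze–target lag stays at the configured 60 ms
anticipatory lead, and the lag-corrected random error (≈1°) reflects the
injected motor noise rather than the systematic delay.

Group-level model comparison on a simulated two-group cohort (29 older + 23
young participants, 12 adaptation trials each):

```r
set.seed(42)
cohort <- simulate_cohort_metrics()            # built from the model structure
mc <- model_comparison_table(cohort)
mc$table
#>                                 Model df   logLik deviance     AIC     BIC
#> 1          Model 1: TC_lag ~ age + TO  7 -3009.52  6019.04 6033.04 6064.09
#> 2 Model 2: TC_lag ~ age + TO + GT_lag  8 -2848.48  5696.95 5712.95 5748.44
#> 3       Model 3: TC_lag ~ TO + GT_lag  7 -2848.49  5696.98 5710.98 5742.04
#> 4     Model 4: TC_lag ~ age + TO + RE  8 -3008.59  6017.18 6033.18 6068.67
#> 5           Model 5: TC_lag ~ TO + RE  7 -3013.91  6027.82 6041.82 6072.87
#> 6  Model 6: TC_lag ~ TO + RE + GT_lag 11 -2845.59  5691.19 5713.19 5761.98

compare_models(mc$fits$m1, mc$fits$m2)
#> LRT: chisq = 322.09, df = 1, p = 5.08e-72
```

Adding the gaze–target lag to the age + trial-order model improves fit
decisively: anticipation carries most of the predictive information about the
tracking lag, which is the package's core inferential comparison.

## Real recordings

Sessions converted to the documented trace schema (a `manifest.json` plus per
trial a 40 Hz hand CSV `t_ms, target_x_px, hand_x_px, cursor_x_px` and a
1000 Hz gaze CSV `t_ms, gaze_x_px, gaze_y_px, pupil_area_px, valid`) load
with `read_session()` and run through the same `run_pipeline()`. Raw
eye-tracker files (e.g. EDF) must be converted externally.
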