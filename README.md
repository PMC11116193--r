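# ibisflight

Processing pipelines for animal-borne sensor data from flying birds —
built around the question of how the shape and attachment position of a
biologging device affect a bird's flight effort. The package covers the
full chain from raw logger signals to the statistics a movement
ecologist reports:

* **Heart rate** — a Pan–Tompkins-style QRS detector (zero-phase 5–40 Hz
  band-pass, squared derivative, moving-window integration, adaptive
  threshold raised during high flight activity), density-based beat
  filtering in the (time, rate) plane, a physiological outlier window,
  and zero-order-hold resampling to a 5 Hz series.
* **VeDBA** — vectorial dynamic body acceleration from tri-axial
  accelerometry: per-axis 1 s running-mean static estimate, dynamic
  residual, Euclidean norm `sqrt(dx² + dy² + dz²)` in milli-g, decimated
  to 1 Hz.
* **Flight segmentation** — flapping vs. gliding from the dynamic heave
  axis (|heave| < 300 mg for at least one wingbeat, 0.2 s), merged with
  heart rate and VeDBA into a 1 Hz session table, summarized by
  experimental condition and by flight mode.
* **Migration distances** — daily great-circle path lengths from GPS
  fixes (haversine, R = 6371 km), the 50 km/day migration–stopover rule,
  and the migration start date (two consecutive qualifying days heading
  toward the breeding site).
* **Models** — the gliding-proportion regression
  `gliding_prop ~ logger_shape × wind_angle + bird` by closed-form OLS,
  and the daily-distance model
  `log10(distance) ~ attachment × activity + (1 | bird)` by
  first-principles REML (profiled 1-D optimization of the variance
  ratio), cross-checked against `lme4`.
* **Synthetic data** — generators for ECG (Gaussian QRS pulses, baseline
  wander, activity-scaled motion artifacts), acceleration (flap/glide
  bouts with gravity drift), and GPS itineraries, all returning their
  latent ground truth so every stage is testable end to end.

## Worked example

Simulate one wind-tunnel flight with alternating flapping and gliding
bouts, run the full pipeline, and summarize by flight mode:

```r
library(ibisflight)

plan <- flight_plan(data.frame(
  state        = c("flap", "glide", "flap", "glide"),
  duration_s   = c(12, 8, 10, 10),
  amplitude_mg = c(800, 60, 750, 80),
  wingbeat_hz  = 5.3
))
acc <- generate_accel(plan, seed = 1)
ecg <- generate_ecg(
  hr_profile(data.frame(time_s = c(0, 40), hr_bpm = c(450, 430)),
             noise_sd_mV = 0.1),
  acc, seed = 2
)

v  <- compute_vedba(acc)                        # 1 Hz VeDBA
hr <- extract_heart_rate(ecg, heave_dynamic = attr(v, "dynamic_heave_mg") / 1000)
st <- classify_flap_glide(attr(v, "dynamic_heave_mg"), acc$sampling_rate)
m  <- merge_streams(hr, v, st, list(
  bird = "310", date = as.Date("2020-08-01"), flight_number = 1,
  logger_shape = "cube", wind_angle = 2
))

head(m[, 1:5])
#>   time_s   hr_bpm vedba_mg state hr_missing
#> 1      0       NA 305.9808  flap       TRUE
#> 2      1       NA 858.6870  flap       TRUE
#> 3      2 448.5981 512.8068  flap      FALSE
#> 4      3 448.5981 520.3830  flap      FALSE
#> 5      4 448.5981 815.1418  flap      FALSE
#> 6      5 446.5116 281.8167  flap      FALSE

gliding_proportion(m)
#> [1] 0.475

flap_glide_summary(list(m))
#>   state n_seconds mean_hr_bpm sd_hr_bpm mean_vedba_mg sd_vedba_mg
#> 1  flap        21    442.5574  5.006681     589.99826   201.54605
#> 2 glide        19    437.5231  5.034786      69.53764    56.40443
```

The 40 s session yields 40 one-second rows (the first two lack a settled
heart-rate hold and are flagged missing). The generated heart rate
(450 → 430 bpm) is recovered to within a few bpm, the gliding share
(18 s of 40, here 0.475 after boundary sampling) matches the plan, and
flapping VeDBA is several times the gliding value — the contrast the
flight-mode summary exists to measure.

For the field-study side, `duration_reduction()` converts two mean daily
migration distances into the percent difference in daily progress:

```r
duration_reduction(130, 113)   # leg-loop vs wing-loop harness, km/day
#> [1] 15.04425
```

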