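---
title: "From raw biologging signals to flight energetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw biologging signals to flight energetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibisflight)
```

## The problem

Biologging devices strapped to flying birds record three synchronized data
streams: a raw electrocardiogram (ECG, millivolts at 1600 Hz), tri-axial
body acceleration (g at 1600 Hz, within a +/- 8 g range), and — for
free-flying birds — GPS fixes.  Heart rate and vectorial dynamic body
acceleration (VeDBA) are the standard proxies for energy expenditure, and
the share of passive gliding versus powered flapping flight is the
behavioural variable that drives both.  `ibisflight` turns those raw
streams into a clean 1 Hz analysis table and fits the associated linear
and mixed models.  Because real wind-tunnel and field recordings are bulky
and not redistributable, the package ships generators that synthesize all
three streams *with known ground truth*, so every processing stage can be
validated end to end.

## Heart-rate extraction

The ECG processing chain is `detect_qrs()` →
`density_filter()` → `remove_outliers()` → `resample_hr()`.

**QRS detection** follows the classic Pan–Tompkins recipe: a zero-phase
5–40 Hz Butterworth band-pass (order 2, applied forwards and backwards so
R-peak positions are not shifted), a squared derivative to emphasize the
steep QRS slopes, moving-window integration (20 ms), and peak picking
above an adaptive threshold with a refractory period of `60 / hr_max`
seconds (75 ms at the default 800 bpm ceiling).  The base threshold is a
fraction (0.3) of the integrated signal's 99th percentile; when a
synchronized dynamic-heave series is supplied, the threshold in each
window is inflated proportionally to the local mean |dynamic heave|
(default 2 per g), because flapping injects motion artifacts into the
electrode signal.  Detected peaks are refined to the local extremum of
the band-passed signal within 30 ms.  A flat-line or structureless trace
(99th percentile less than 8 times the median of the integrated signal)
returns an *empty* beat series with a diagnostic attribute rather than an
error, so batch processing can skip bad sessions gracefully.

**Density filtering** ranks each beat by the number of other beats within
+/- 2 s and +/- 20 bpm and keeps the top 95% (all defaults configurable).
Physiological heart rate evolves slowly, so genuine beats form dense
bands in the (time, rate) plane while false detections land in sparse
regions.  Ties at the cutoff count are all kept, so at least
`ceiling(keep_fraction * n)` beats survive and a single beat always
survives.  The implementation uses a sorted two-pointer sweep
(O(n·window)); tests verify exact equality with an all-pairs brute-force
count up to 500 points.

**Outlier removal** is a fixed physiological window (60–800 bpm).  The
original workflow this emulates deleted outliers by eye; a deterministic
window makes the pipeline reproducible at the cost of not catching
in-range artifacts — which the density filter handles.

**Resampling to 5 Hz** uses a zero-order hold of the most recent
completed inter-beat interval.  A hold was chosen over linear
interpolation so that no values are invented inside detection gaps; grid
points more than `max_gap` (default 2 s) after the last beat are emitted
as missing.  All timestamps are seconds from the session start on the
ECG clock; the ECG and accelerometer are co-housed in one logger, so no
cross-device synchronization model is needed.

## VeDBA

Each acceleration axis is smoothed with a centered 1 s running mean to
estimate the static (gravity + posture) component; the dynamic component
is raw minus static, and VeDBA is the per-sample Euclidean norm of the
three dynamic axes, reported in milli-g.  Two deliberate readings of
ambiguous convention:

* **Edge policy.** The running mean uses shrinking (truncated) centered
  windows at the trace ends, so output length equals input length and no
  padding values are invented.
* **Sub-sampling.** The 1 Hz VeDBA series is literal decimation — the
  sample nearest each integer second — not block averaging, since the
  downstream merge is defined on instantaneous timestamps.  The 1 Hz
  grid is anchored to integer seconds of the session clock (every fifth
  point of the 5 Hz heart-rate grid therefore aligns exactly).

## Flight segmentation

Gliding is any maximal run with |dynamic heave| < 300 mg lasting at least
one wingbeat (0.2 s); shorter sub-threshold runs — for example the brief
dwells around the wingbeat oscillation's zero crossings, about 25 ms per
half-cycle at 5 Hz and 800 mg — are relabeled flapping.  Relabeling runs
once, with no iterative merging.  The 1 Hz merge takes the instantaneous
state at each VeDBA timestamp, not a majority vote over the second, and
flags rows whose heart-rate sample is missing.  `condition_summary()` and
`flap_glide_summary()` then aggregate sessions by experimental condition
(logger shape × wind angle) and by flight mode.

## GPS distances and migration

Daily flight distance is the connected great-circle path over the day's
fixes, using the haversine formula on a sphere of radius 6371 km — the
error against a full ellipsoid is far below 1% at the 10–200 km daily
scale.  Fixes are bucketed by civil date in `Europe/Rome` (one zone
covers the whole migration corridor; configurable), and segments spanning
midnight are credited to neither day but counted for audit.  A day is a
*migration day* when its path reaches 50 km (inclusive); the *migration
start* is the first of two consecutive days that both qualify **and**
both head toward the breeding site, operationalized as the day's
net-displacement bearing lying within +/- 90 degrees of the bearing to
the breeding site (no tolerance angle is standard; +/- 90 degrees is the
half-plane "toward").  `duration_reduction()` converts two mean daily
distances into the percent difference in daily progress, which for a
fixed-length journey equals the relative reduction in migration duration.

## Statistical models

Two models are implemented from first principles:

* **OLS** (`fit_ols()`): QR-based closed-form least squares with
  classical standard errors, R² and the overall F statistic.  Used for
  the gliding-proportion model
  `gliding_prop ~ logger_shape * wind_angle + bird` (treatment coding;
  references cube, +2°, first bird), one observation per flight session.
* **Random-intercept LMM by REML** (`fit_lmm_ranint()`): the model
  `y = Xb + u[group] + e` has a single variance ratio
  λ = σ²_group / σ²_resid, and for a random intercept the per-group
  inverse `V⁻¹ = I − λ/(1+λn_i) J` gives closed forms for the GLS fixed
  effects, the profiled residual variance and the REML criterion.  The
  fit is therefore a 1-D minimization of the profiled criterion over
  log λ (Brent search), with the λ = 0 boundary evaluated explicitly so
  that a data set with no between-group variance degenerates *exactly*
  to OLS.  Tests verify agreement with `lme4::lmer` to 1e-6 on fixed
  effects, standard errors and variance components, and with the
  closed-form ANOVA estimators in the balanced one-way case.  Used for
  the field-study model
  `log10(distance) ~ attachment * activity + (1 | bird)` (references
  wing-loop, stopover), after excluding zero-distance days that cannot
  be log-transformed (their count is reported).

Reported t-values use residual degrees of freedom; no Satterthwaite
small-sample correction is applied, which matters little at ~1000
observations but should be kept in mind for small designs.  Generalized
additive mixed models (smooth terms, AR1 residual structure) are out of
scope by design: the package's job ends at the tidy 1 Hz merged table
such models consume.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Acceleration** (`generate_accel()`): heave = 1 g gravity, optionally
  tilted by a slow sinusoidal orientation drift (default +/- 10° at
  0.1 Hz, slow enough to pass through the 1 s static window) + a
  per-segment wingbeat oscillation (default 5 Hz, the rate implied by a
  0.2 s wingbeat) + white noise (default 20 mg SD).  Surge and sway carry
  attenuated phase-shifted copies of the oscillation.  Flap segments use
  amplitudes above 300 mg, glide segments below, as the classifier
  assumes.
* **ECG** (`generate_ecg()`): Gaussian R-peaks (default width 8 ms,
  amplitude 4 mV — the simplest shape a QRS detector must still find) at
  beat times given by integer crossings of the integrated instantaneous
  rate, plus baseline wander (0.3 mV at 0.25 Hz), white noise, and a
  motion artifact equal to `artifact_gain` (mV/g) times the clean dynamic
  heave.  Profiles whose RR interval would fall below 3 QRS widths are
  rejected as unresolvable.
* **GPS** (`generate_gps_track()`): migration days trace one great-circle
  leg toward the breeding site (or rotated by a per-day bearing offset,
  which creates direction-violating decoys for testing the start-date
  rule); stopover days are out-and-back foraging loops returning to the
  day's start.  Per-fix jitter is 15 m SD, negligible at the 50 km
  decision scale, so generated path lengths recover their targets within
  1%.

What the generators deliberately do **not** emulate: realistic PQRST
morphology, heart-rate variability, aerodynamic coupling between flight
mode and heart rate, GPS dropout, or fix-rate heterogeneity between
devices.  Passing tests therefore demonstrate the *computational*
correctness of each stage and the recoverability of known structure —
not that the detector's defaults are optimal for any particular species'
ECG morphology.

## Problem sizes and numerical choices

The validation suite runs on 30–120 s sessions at the full 1600 Hz rate,
50 randomized flight plans, 20 randomized itineraries, and 200-replicate
recovery studies for both models (26 sessions for the OLS design; 37
birds × ~28 days, matching the field study's 1060 bird-days, for the
LMM) — sizes chosen so the whole suite completes in well under a minute
while every stage still operates at the data rates it was designed for.
Degenerate inputs are handled explicitly: flat ECG yields an empty beat
series, single GPS fixes yield zero path length, a single beat survives
density filtering (ceiling rule), and rank-deficient designs are
reported as errors rather than silently dropped columns.

## Known limitations

* The density filter's window sizes and keep fraction are stated
  defaults, not values recovered from any original workflow; they are
  configurable and the filter's behaviour is specified exactly.
* The 50 km rule uses civil-date bucketing in a single time zone; birds
  crossing zone boundaries at midnight could have a day's distance split
  differently.
* `fit_lmm_ranint()` supports exactly one random intercept — the model
  it exists for — not nested or crossed random effects.
* The QRS detector assumes a dominant R deflection; heavily inverted or
  biphasic morphologies would need a different refinement step.
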