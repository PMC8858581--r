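---
title: "Detecting whale-calf suckling from accelerometer and depth data: methods"
author: "suckletag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting whale-calf suckling from accelerometer and depth data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suckletag)
```

## The problem

Humpback whale calves suckle in brief, rare bouts: roughly 19 s at a time,
one to two percent of the day, mostly at depth, and nearly always rolled
far onto one side so the mouth can reach the mother's mammary slit. On an
animal-borne tag that carries only a triaxial accelerometer and a depth
sensor, that behavior leaves a kinematic fingerprint — sustained absolute
roll, near-horizontal pitch, slightly elevated fluke stroke rate (FSR) and
reduced speed — which is what this package detects.

`suckletag` implements the full chain from raw tag record to detector:

1. **Kinematics** — 10 Hz channels (depth rate, speed, FSR, ODBA, pitch,
   roll, roll rate) derived from the acceleration and depth streams.
2. **Dive phases** — surface / descent / bottom / ascent segmentation.
3. **Event products** — per-event feature records, time budgets, event
   clusters, dive-type counts, and random non-suckling comparison segments.
4. **Block features** — non-overlapping 2 s windows summarized by 43
   statistical features, with the shallow/fast exclusion filter.
5. **Detection** — a natively implemented AdaBoost.M1 over depth-limited
   trees, evaluated by repeated stratified holdout, leave-one-individual-out
   (LOIO) splits, and random-forest Gini-importance feature pruning.
6. **Synthetic deployments** — a generator with known ground truth, so every
   stage above is testable without field data.

## Frame and sign conventions

All computations share one body frame: x forward, y right, z up. Level
posture reads (0, 0, +1) g; pitch is positive nose-up
(`pitch = asin(ax/|a|)`); roll is positive right-side-down
(`roll = atan2(ay, az)`); depth is positive downward, so depth rate is
positive while descending. The generator simulates directly in the animal
frame; tag-to-animal rotation (a magnetometer/gyroscope problem) is out of
scope, but `rotate_stream()` provides a fixed-rotation hook so the
pass-through can be tested.

## Sensor processing and its parameters

All parameters live in `pipeline_config()`; the defaults below are the
reference processing conditions.

| parameter | default | meaning |
|---|---|---|
| `depth_median_s` | 0.5 s | running-median smoothing of depth |
| `posture_lowpass_hz` | 0.2 Hz | low-pass separating posture from strokes |
| `stroke_band_hz` | 0.2–1 Hz | band isolating the fluke-stroke pitch oscillation |
| `stroke_thresh_deg` | 3° | half-stroke detection threshold |
| `stroke_max_transit_s` | 6.5 s | slowest admissible threshold-to-threshold transit |
| `dive_depth_m` | 10 m | minimum maximal depth of a dive |
| `surface_threshold_m` | 1 m | submergence crossing that bounds a dive |
| `bottom_frac` | 0.85 | bottom phase: deeper than 85% of max dive depth |
| `segment_len_s`, `nonsuckling_per_phase` | 20 s, 10 | comparison segments |
| `block_len_s`, `block_label_frac` | 2 s, 3/5 | classification blocks and label rule |
| `excl_depth_m`, `excl_speed_ms` | 1.5 m, 2 m/s | block exclusion filter |
| `odba_window_s` | 3 s | static-acceleration window for ODBA |

Channel definitions:

* **Pitch/roll.** The high-rate acceleration is block-averaged onto the
  10 Hz depth clock; that static vector gives raw pitch and roll. A
  zero-phase 4th-order Butterworth low-pass at 0.2 Hz yields the posture
  channels (roll is unwrapped before filtering and rewrapped after).
* **Stroke signal and FSR.** Raw pitch band-passed at 0.2–1 Hz; a
  half-stroke fires when the signal leaves one ±3° threshold region and
  reaches the opposite one within 6.5 s, so consecutive half-strokes
  alternate polarity. Between half-strokes spaced Δ ≤ 6.5 s the FSR is held
  at 1/(2Δ) full strokes per second, and 0 elsewhere. Holding the
  instantaneous rate (rather than counting strokes in windows) keeps 2 s
  block means off the coarse quantization grid.
* **ODBA.** Static acceleration is the per-axis 3 s centered running mean;
  ODBA is the sum over axes of the absolute dynamic residual, block-averaged
  to 10 Hz and converted to m/s². The 3 s window sits between the posture
  band and the 0.2–1 Hz stroke band, which the original ODBA formulation
  leaves unspecified.
* **Depth rate.** Central first difference of the smoothed depth times the
  rate, then a 0.5 s running mean; positive = descending.
* **Roll rate.** Absolute first difference of the unwrapped roll, smoothed
  0.5 s. It is reported as an unsigned magnitude because a signed rate
  averages to ~0 over any roll-and-return excursion, which would make the
  per-event means meaningless.
* **Speed.** When the tag provides a speed channel it is passed through a
  0.5 s running mean. Otherwise speed comes from tag jiggle: the ≥10 Hz
  content of the acceleration norm, summarized as a windowed RMS `J`;
  calibration samples where |posture pitch| ≥ 30° and |depth rate| > 0.3 m/s
  provide the orientation-corrected depth rate OCDR = |depth rate / sin
  pitch| as an independent speed estimate, and `ln(OCDR) = a + b·J` is fit
  by least squares and applied everywhere. This is a deliberately simple
  single-fit version of the jiggle method; with fewer than 50 calibration
  samples, or jiggle with no variance, the estimator refuses and asks for a
  precomputed channel. Note that because `J` is itself a windowed estimate,
  the fitted slope is attenuated relative to the noise-free jiggle–speed
  relation (classical errors-in-variables); predictions are unaffected
  because they use the same noisy `J`.

### Numerical choices

The filter design (unspecified in the underlying method descriptions) is a
zero-phase 4th-order Butterworth everywhere — the standard biologging
choice, because forward–backward filtering preserves event timing. Since
forward–backward IIR filtering has a start-up transient, every filtered
series is odd-reflection padded at both ends and trimmed, so a constant
input passes through essentially unchanged and record edges are usable.
Running means/medians shrink their windows at the edges. Block moments use
the conventions of the original analysis environment: variance with n−1,
skewness `m3/m2^1.5` and non-excess kurtosis `m4/m2²` from biased central
moments; constant windows get skewness and kurtosis 0 rather than NaN.
Zero-denominator evaluation metrics are returned as `NA` (an explicit
undefined flag) and dropped from run averages with their count noted —
never silently zeroed.

## Dive phases

A dive is a maximal submergence between a downward and the next upward
crossing of the 1 m surface-proximity threshold, retained only if its
maximal depth exceeds 10 m; everything else is surface, including
sub-10 m excursions (real surface suckling happens around 6 m depth). The
1 m boundary is a design choice — the dive criterion itself only pins the
10 m rule — and makes dive edges robust to surface chop. Within a dive the
bottom phase spans the first-to-last sample deeper than 85% of the maximal
depth: a single contiguous bottom, so a stop at an intermediate depth
between two deep lobes stays in the bottom phase. Descent and ascent flank
it.

## Event products

Per-event records average each channel over `[start, stop)`; roll enters as
the mean absolute posture roll (deviation from zero regardless of side) and
the activity phase is the majority phase over the event, with ties broken
by the phase at the event start (whether the original 20 s segment phases
used majority or full containment is not documented; majority is the
weaker, safer assumption). Non-suckling comparison segments come from a
fixed 20 s grid anchored at t = 0, keeping segments with zero overlap with
any suckling event and drawing 10 per activity phase in which suckling
occurred. Event clusters chain events whose gap is under 60 s. The suckling
budget is the percentage of recording time inside events.

## Blocks and the exclusion filter

The record is cut into non-overlapping 2 s blocks (trailing partial block
dropped). A block is labelled suckling when at least 3/5 of its duration
overlaps suckling events — the boundary is inclusive (12 of 20 samples
suffice), a choice the 3/5 rule's wording leaves open. Each block gets 43
features: mean, min, max, variance, skewness, kurtosis for depth, depth
rate, speed, ODBA, pitch, absolute roll and roll rate, plus the mean FSR.
Blocks with mean depth < 1.5 m or mean speed > 2 m/s are excluded — the
thresholds are applied to block means, the least noisy single-block summary
— and `filter_blocks()` reports whether any suckling block was lost, which
on valid data (and by construction on synthetic data) must be zero.

## The detector

AdaBoost.M1 is implemented natively: uniform initial weights; each round
fits a depth-limited `rpart` tree on the weighted sample; with weighted
error `e`, the round coefficient is `alpha = ln((1−e)/e)`; misclassified
weights are multiplied by `exp(alpha)` and renormalized; training stops
early at `e ≥ 0.5` (warning if the ensemble is empty) or `e = 0` (alpha
capped at `ln((1−1e-10)/1e-10)`); prediction is the sign of the weighted
vote, ties to the negative class. Suckling is the positive class and no
resampling or class weighting is added beyond boosting's own reweighting —
boosting handles the ~4% positive share, and the evaluation emphasizes the
false-positive rate rather than global accuracy. `select_model()` is a
pluggable seeded-search harness over hyperparameter candidates scored by
stratified 5-fold cross-validated misclassification; the full external
model zoo (KNN variants, SVM kernels, a dozen boosting flavors) is out of
scope. On the reference cohort the selection lands on 40 rounds of depth-3
trees, which the experiment drivers use throughout.

Evaluation: `repeated_holdout()` runs seeded stratified splits (per-class
shuffling, train counts rounded per class) and averages the metric set —
sensitivity TP/(TP+FN), precision TP/(TP+FP), FPR = 1 − TN/(TN+FP), F-score
2TP/(2TP+FP+FN), global accuracy — across runs. `leave_one_individual_out()`
trains on all-but-one individual and evaluates on the held-out one,
reporting per-combination class balances.

## Feature pruning for generalization

`rank_features_by_individual()` trains a random forest to classify the
*individual* from the suckling blocks alone; a low out-of-bag (OOB) error
means the calves are easy to tell apart from their suckling kinematics, and
the Gini (mean impurity decrease) ranking names the features responsible.
`exclude_by_knee()` cuts that ranking either at the largest consecutive
drop (`knee`) or above a threshold τ. The experiment drivers use the
threshold mode with τ = mean importance: on smoothly decaying profiles the
single largest gap can fall inside the individual-signal block, while the
mean sits reliably between that block and the tail of
behavior-discriminative features. On the reference cohort this removes the
mean/min/max (and variance) features of depth, pitch and speed — exactly
the channels that carry the constructed individual offsets — after which
the individual-ID OOB error rises from ~0% to ~40% and mean LOIO
sensitivity improves (0.80 → 0.88 on the reference cohort). The improvement
is conditional: it is large when the all-features model generalizes poorly
(the situation pruning is meant to fix) and can be nil on cohort
realizations whose full model already transfers well.

## The synthetic generator

`generate_deployment()` builds a 10 Hz schedule (depth, posture pitch,
roll, speed, stroke rate) from a dive/surface timeline and then synthesizes
the high-rate acceleration as gravity projected through the scheduled
posture, plus a sinusoidal stroke oscillation, speed-proportional jiggle
noise, and sensor noise. Defaults are the package's reference study
conditions:

* **Dive cycles**: ~5 dives/h with maximal depths 12–33 m, 0.9 m/s vertical
  rates, a bottom phase near 45% of the dive; surface time alternates
  logging at ~0.4 m with shallow (2–6 m) swimming excursions. Surface
  intervals and dive durations follow plausible placeholder distributions —
  the study conditions do not pin them.
* **Strokes**: pitch oscillation of 4.2° at 0.26–0.36 Hz, inside the
  analysis band with enough margin that the band-passed signal clears the
  ±3° threshold; the implied ODBA then sits near the top of the observed
  0.2–0.6 m/s² event range.
* **Suckling**: scheduled per dive with probability 0.3 as clusters of 2–6
  events (sizes weighted toward 2–3) with alternating roll sides, plus
  occasional shallow-dip clusters during long surface intervals; durations
  N(18.8, 8.8²) s truncated above 2 s; roll plateaus of 30–60° with a slow
  jostle; near-zero pitch; reduced speed (1.0–1.55 m/s band); a +0.05 Hz
  stroke-rate elevation. Events are never scheduled during ascent. The
  posture ramps into and out of an event (~5 s) sit just outside the
  labelled interval, because a video label starts at snout contact, after
  the calf has already rolled into position. Ten-seed mean truth budget:
  ~1.75% of recording time. Every scheduled event keeps depth ≥ 1.5 m and
  speed ≤ 2 m/s, so the exclusion filter provably removes none — mirroring
  the validated assumption on real data.
* **Confounds**: brief banking rolls (10–40°, 3–10 s) and sustained
  non-suckling side rolls drawn from the *same* roll distribution as
  suckling (8–30 s, with the same slow jostle; 35% of them also carry the
  stroke-rate elevation, as active play would). Without them a roll
  threshold alone would separate the classes perfectly, which real data
  does not permit.
* **Individuals**: `generate_cohort()` applies per-individual additive
  offsets to depth, pitch and speed, creating inter-individual variability
  in exactly the channels whose summary features the pruning step later
  removes; roll and FSR signatures are shared. The reference offsets span
  the spread observed across real calves.

What the generator does **not** emulate: tag-frame misalignment and its
correction, magnetometer/gyroscope channels, hydrodynamic or wave noise
structure, mother–calf interaction dynamics, acoustic cues, diel behavioral
trends, and any behavior classes beyond the suckling/roll-confound/cruise
repertoire above. Passing tests on synthetic data therefore demonstrate
that the pipeline's machinery is correct and that the detection approach
recovers a planted signature under realistic rarity, noise and
inter-individual variability — not that a tag on a new animal will yield
the same metric values.

## Experiment sizes

The reference experiments use three 4 h deployments (432,000 10 Hz samples,
~21,600 blocks, ~14,000 after filtering, ~4% suckling), six repetitions per
holdout fraction, and 500-tree forests; these sizes give stable means while
keeping the full suite and the acceptance script quick to re-run. The
deployment generator and all experiment harnesses take explicit seeds;
experiment-level seeds derive per-run seeds by fixed offsets, so every
reported number is reproducible.

## Known limitations

* The jiggle speed calibration needs steep, moving dive segments; a
  deployment of pure surface travel must supply a precomputed speed channel.
* FSR is undefined (held at 0) during glides; event means over mixed
  glide/stroke intervals are diluted accordingly.
* The half-stroke rule requires full transits between opposite thresholds;
  re-crossings without reaching the opposite threshold are ignored, which
  is one admissible reading of the threshold rule.
* Metrics from single LOIO combinations are one-model estimates; their
  spread across cohort realizations is substantial, and the pruning gain is
  conditional as described above.
* The exclusion filter's validity check is a property of the data it is run
  on; on new animals it must be re-verified, not assumed.
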