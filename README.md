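# suckletag

Detecting suckling behavior in humpback whale calves from animal-borne tag
data — triaxial accelerometer plus depth sensor only.

Suckling in baleen whale calves is vital, brief (~19 s), rare (~1–2% of the
day) and nearly impossible to observe directly: it happens underwater,
mostly during dives, with the calf rolled far onto one side to reach the
mother's mammary slit. Multi-sensor tags with cameras can confirm it, but
most tags — and most recorded hours, including all of the night — have no
usable video. `suckletag` is for biologging researchers who want to detect
those events from the kinematic channels alone: it derives the channels,
segments the dive cycle, characterizes annotated events, and trains and
evaluates an automatic detector, with a synthetic-deployment generator
providing ground truth so the whole chain is testable without field data.

## What it computes

From a tag record (acceleration in g at ≥ 20 Hz, depth at 10 Hz) the
package derives index-aligned 10 Hz channels: smoothed depth and depth rate;
pitch and roll (`pitch = asin(a_x/|a|)`, `roll = atan2(a_y, a_z)`), with
0.2 Hz low-passed posture versions; the 0.2–1 Hz band-passed fluke-stroke
signal, half-strokes (±3° threshold transits within 6.5 s) and the fluke
stroke rate FSR = 1/(2Δ) between half-strokes; ODBA (sum of absolute
dynamic acceleration, 3 s static window, in m/s²); roll rate; and forward
speed from tag jiggle calibrated against the orientation-corrected depth
rate, ln(OCDR) = a + b·J.

Dives are submergences exceeding 10 m; the bottom phase is the span deeper
than 85% of the dive's maximal depth, descent and ascent flank it, and
everything else is surface. Behavioral events are summarized as per-event
channel averages (roll as mean |roll|), time budgets, clusters (< 60 s
apart), and suckling/non-suckling dive counts, with random 20 s
non-suckling segments for comparison.

For detection, the record is cut into 2 s blocks labelled suckling when at
least 3/5 of the block overlaps an event, each summarized by 43 features
(six moments × seven channels + mean FSR); blocks shallower than 1.5 m or
faster than 2 m/s are excluded, with a validity report proving no suckling
block was lost. The detector is a natively implemented **AdaBoost.M1** over
depth-limited trees (round weight `α = ln((1−ε)/ε)`), evaluated by

- Sensitivity = TP/(TP+FN), Precision = TP/(TP+FP),
- FPR = 1 − Specificity, Specificity = TN/(TN+FP),
- F-score = 2TP/(2TP+FP+FN), Global accuracy = (TP+TN)/total,

under repeated stratified holdout (60:40 … 10:90), leave-one-individual-out
(LOIO) splits, and random-forest Gini-importance pruning of the features
that encode individual identity.

## Worked example

```r
library(suckletag)

# simulate a 20-minute deployment with known ground truth
dep <- generate_deployment(synthetic_config(duration_s = 1200, seed = 42))
dep
#> <synthetic_deployment> Calf1: 0.3 h, 1 dives, 2 suckling events (3.95% of time)

# derive the 10 Hz kinematic channels and the dive phases
kin <- compute_kinematics(dep$stream)
kin
#> <kinematic_series> Calf1: 12000 samples @ 10 Hz (20.0 min), 770 half-strokes
phases <- segment_phases(kin)
phases
#> <phase_annotation> 1 dives; samples: surface=10360, descent=299, bottom=1043, ascent=298

# per-event feature records (video annotations would normally supply events)
records <- events_feature_table(kin, phases, dep$truth_events)
records[, c("phase", "duration_s", "avg_depth_m", "avg_abs_roll_deg",
            "avg_fsr_hz", "avg_speed_ms")]
#>    phase duration_s avg_depth_m avg_abs_roll_deg avg_fsr_hz avg_speed_ms
#> 1 bottom   24.39636    32.35992         48.27500  0.3661502     1.581475
#> 2 bottom   23.04340    32.37170         43.97445  0.3912754     1.630360

suckling_budget(dep$truth_events, 1200)
#> [1] 3.953314

# 2-s blocks with 43 features, labelled and filtered
blocks <- make_blocks(kin, dep$truth_events, phases)
fl <- filter_blocks(blocks)
unlist(fl$report)
#>           n_before            n_after n_suckling_removed               pass
#>                600                334                  0                  1

# evaluation metrics from a confusion matrix
unlist(compute_metrics(c(tp = 90, tn = 2998, fp = 8, fn = 34)))
#>     sensitivity       precision             fpr     specificity         f_score
#>     0.725806452     0.918367347     0.002661344     0.997338656     0.810810811
#> global_accuracy
#>     0.986581470
```

Both events sit on the dive's bottom phase with sustained |roll| around
44–48°, mildly elevated FSR and reduced speed — the suckling signature the
detector learns. The exclusion filter removed 266 surface blocks and, as
required, zero suckling blocks.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on a reference
3-individual, 4 h-each synthetic cohort and write summary tables to
`results/` (large intermediates go to `scratch/`):

```sh
Rscript analysis/01_simulate.R            # cohort + ground-truth summary
Rscript analysis/02_kinematics_phases.R   # channel/phase recovery vs truth
Rscript analysis/03_event_features.R      # event records + comparison segments
Rscript analysis/04_blocks.R              # 43-feature block table + filter report
Rscript analysis/05_detection.R           # model selection, holdout, size curve
Rscript analysis/06_generalization.R      # LOIO + Gini-importance pruning
```

On the reference cohort the detector reaches F ≈ 0.96 at 60:40 with FPR
< 0.2%, declines gradually to F ≈ 0.90 at 10:90, and LOIO sensitivity rises
from 0.80 to 0.88 after pruning the ten features that let a random forest
identify individuals from suckling blocks (OOB error ~0% → ~40%).

## Documentation

The methods vignette (`vignettes/suckling-detection-methods.Rmd`) describes
the processing chain, every tunable parameter with its default and
rationale, the synthetic generator's design and what it does and does not
emulate, the numerical choices, and known limitations.
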