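# stspipe

Integrated analysis of **sit-to-stand (STS) movements** from three
simultaneously recorded but unsynchronized sensor streams:

- bilateral surface EMG of the **erector spinae** (lumbar load proxy),
  1000 Hz, with button-press event timestamps;
- balance-board **center of pressure** (COP: anterior–posterior,
  medio-lateral, total load), 100 Hz;
- depth-camera **3D joint coordinates** (pelvis, neck, head, left hand),
  30 Hz, with missing frames.

The package targets studies of lumbar load during assisted standing — for
example comparing hand-support strategies (hands on knees, one hand on a
table, both hands on a table) and the effect of a weighted
maternity-simulation jacket worn as a within-subject factor. Because such
recordings are rarely shareable, the package also ships a synthetic session
generator that reproduces the whole study protocol with known ground truth,
so every processing stage is testable end to end.

## What it computes

**EMG envelope.** Each raw channel `x` is band-limited with a zero-phase
4th-order Butterworth band-pass (5–30 Hz), full-wave rectified about its
mean, smoothed with a centered moving average
`x_mv(t) = (1/(2L+1)) Σ_{i=−L..L} x(t−i)` (L = 10 samples), and min–max
scaled so the recording's maximum is exactly 100 and minimum exactly 0
(used in place of %MVC scaling when no maximum voluntary contraction is
available).

**Alignment.** All streams are resampled to a common 1000 Hz clock
(linear interpolation, missing skeleton frames stay missing). Inter-stream
clock offsets are estimated from the protocol's synchronization gestures:
three left-hand raises matched to three button presses give the
joint-vs-EMG offset `D_cj,EMG = (1/3) Σ_k D_k`, and three toe stands
(head-height apex vs forward-COP apex) give the joint-vs-COP offset
`D_cj,COP`, each the mean of three per-event time differences. Apexes are
localized with prominence-filtered peak detection and sub-sample parabolic
refinement.

**Segmentation.** Each stand-up epoch runs from the sitting instant (local
minimum of pelvis height) to the standing instant (subsequent maximum of
head height). An epoch is excluded when all joints are missing in at least
half of its camera frames.

**Features per epoch.** Integrated EMG (`iEMG`, trapezoidal integral of the
envelope, %·s), maximum EMG (%), mean anterior–posterior COP (mm), and
maximum trunk flexion angle — the angle between the pelvis→neck segment and
vertical-up, in degrees.

**Statistics.** Per-subject repetition means enter paired t-tests
(left vs right EMG per condition; jacket vs no jacket for each feature and
condition), one-way repeated-measures ANOVAs across the three support
conditions, and Benjamini–Hochberg correction for the three pairwise
trunk-angle condition comparisons.

## Worked example

```r
library(stspipe)

cfg <- sim_config(seed = 1)                 # study-protocol defaults
session <- generate_session(cfg, subject_id = 1)
session
#> <sts_session> subject 1: EMG 1000 Hz x2, COP 100 Hz, skeleton 30 Hz, 6 blocks

al <- align_session(session)                # offsets + 1000 Hz master clock
al$sync
#> <sts_sync> D_cj,EMG = 0.5006 s  D_cj,COP = -0.3025 s
# (the generator's true offsets were 0.5 and -0.3 s)

epochs   <- segment_session(al$session, al$skel_native)
features <- build_feature_table(al$session, epochs)
head(features[, c("condition", "jacket", "rep", "iemg_left",
                  "iemg_right", "mean_cop_ap", "max_trunk_angle")], 4)
#>             condition jacket rep iemg_left iemg_right mean_cop_ap max_trunk_angle
#> 1 both-hands-on-knees  FALSE   1    16.455      16.37       19.37           43.47
#> 2 both-hands-on-knees  FALSE   2    19.253      22.91       18.77           41.31
#> 3 both-hands-on-knees  FALSE   3    19.473      19.29       19.20           43.53
#> 4   one-hand-on-table  FALSE   1     9.415      11.69       19.04           29.10
```

iEMG is the integral of the 0–100-scaled envelope over each epoch (%·s);
`mean_cop_ap` is in mm anterior of the board origin; the trunk flexes ~40°
in two-hand conditions and less when one hand rests on the table.

A cohort-level statistical battery (here on a simulated 10-subject feature
table with the default injected jacket effects — EMG amplitude × 1.5, COP
−15 mm, trunk angle unchanged):

```r
ft  <- simulate_feature_cohort(n_subjects = 10, seed = 1)
res <- run_sts_comparisons(ft)
res[c(7, 13, 16, 21), c("comparison", "statistic", "df", "p", "p_adjusted")]
#>                                                  comparison statistic df        p p_adjusted
#> 7            iemg_mean jacket vs none | both-hands-on-knees      8.86  9 9.67e-06         NA
#> 13         mean_cop_ap jacket vs none | both-hands-on-knees     -8.36  9 1.56e-05         NA
#> 16     max_trunk_angle jacket vs none | both-hands-on-knees      0.19  9 8.53e-01         NA
#> 21 max_trunk_angle both-hands-on-knees vs one-hand-on-table     28.11  9 4.44e-10   1.33e-09
```

The jacket raises iEMG (t = 8.9, p < 1e-5) and shifts the mean COP
posteriorly (t = −8.4), while the trunk angle shows no jacket effect
(p = 0.85) — the qualitative pattern the pipeline is built to detect.

A command-line wrapper around the same functions lives at
`inst/scripts/sts` (`sts sim`, `sts validate`, `sts run`); see
`?sts_main`.

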