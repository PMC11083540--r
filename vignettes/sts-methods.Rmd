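---
title: "Methods: multimodal sit-to-stand analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal sit-to-stand analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stspipe)
```

## The measurement problem

A sit-to-stand (STS) study of lumbar load records three streams that never
share a clock: surface EMG of the left and right erector spinae (1000 Hz),
balance-board center of pressure (COP, 100 Hz), and depth-camera joint
coordinates (30 Hz). The protocol provides its own synchronization
gestures before the trials proper: the subject raises the left hand and
presses a button on the EMG unit three times (pairing the joint stream
with the EMG clock), then performs three toe stands (pairing the joint
stream with the COP clock, whose forward coordinate peaks as the heels
leave the board). Six condition blocks follow — three hand-support
strategies (both hands on knees, one hand on a table, both hands on a
table), each performed with and without a weighted maternity-simulation
jacket — with three stand-ups per block.

`stspipe` implements the full chain from raw streams to the statistical
battery, plus a synthetic-session generator that reproduces this protocol
with known ground truth.

## EMG envelope

Each channel passes through four stages:

1. **Band-pass** 5–30 Hz, 4th-order Butterworth, applied forward–backward
   (`signal::filtfilt`). The zero-phase realization preserves burst
   timing, which segmentation-aligned comparisons rely on; its effective
   magnitude response is the squared single-pass response, comfortably
   meeting a ≥ 90 % in-band / ≤ 10 % out-of-band amplitude contract at
   1000 Hz.
2. **Full-wave rectification**: subtract the channel mean, take absolute
   values. `emg_rectify(abs = FALSE)` stops after centering, for
   protocols that define rectification as mean removal only.
3. **Moving average** with the symmetric window
   $x_{mv}(t) = \frac{1}{2L+1}\sum_{i=-L}^{L} x(t-i)$, default
   $L = 10$ samples (a 21 ms window at 1000 Hz). At the edges the window
   truncates to the available samples, preserving signal length without
   inventing padding.
4. **Min–max scaling** to exactly [0, 100], per channel over the whole
   recording and *before* segmentation. Recording-wide scaling stands in
   for %MVC normalization when a maximum voluntary contraction is
   unavailable; scaling per epoch instead would destroy between-epoch
   comparability of iEMG.

**Stage order.** Listing rectification before filtering is common in
protocol descriptions, but executing the stages in that order removes the
information the envelope exists to carry: rectification is what shifts
burst energy toward 0 Hz, so a subsequent 5–30 Hz band-pass strips the
slowly varying envelope component (an STS burst lasting ≈ 1 s has its
envelope content well below 5 Hz) and leaves a zero-mean residual whose
integral no longer tracks activation amplitude. We verified this
directly: on Gaussian-windowed band-limited bursts of known amplitude,
per-epoch iEMG correlates with the injected amplitude at Spearman ≈ 0.9
when filtering precedes rectification, and ≈ 0 (slightly negative) when
it follows. `sts_envelope()` therefore filters first by default;
`order = "rectify-first"` reproduces the literal listed order for
comparison.

A constant raw recording is rejected with a degenerate-range error (it
cannot be min–max scaled, and zero-phase filtering of a constant produces
only edge transients); degeneracy is detected with a relative tolerance
of $10^{-12}$.

## Alignment

**Resampling** is linear interpolation onto a uniform 1000 Hz grid
spanning each stream's range — the minimal-assumption choice, exact for
piecewise-linear signals and with $O((2\pi f/f_s)^2/8)$ amplitude error
for band-limited kinematics. A skeleton joint is missing at an output
time whenever either bracketing camera frame has it missing: missingness
widens, and is never interpolated across.

**Event detection** (`detect_peaks`) finds local maxima, filters them by
topographic prominence (default ≥ 25 % of the searched window's range)
and minimum separation (default 1 s — the protocol gestures are
deliberate and slow), and returns the first *n* in temporal order. Two
numerical choices matter:

- *Sub-sample refinement.* A least-squares parabola over ±0.15 s around
  the discrete argmax localizes a smooth apex far below the 33 ms frame
  period of the 30 Hz stream; without it, the mean of three per-event
  differences could not reliably reach millisecond-scale offset accuracy.
  The refinement falls back to the grid time when the local fit is not
  concave.
- *Pre-smoothing.* Inside `sync_session()` each searched trace is first
  smoothed with a symmetric ~80 ms moving average, so single-sample
  sensor noise cannot manufacture a prominent "peak" in the quiet
  stretches of the synchronization window. Symmetric smoothing does not
  shift symmetric apexes.

`estimate_offset()` is deliberately rigid: the protocol fixes exactly
three events per stream pair, and the offset is the arithmetic mean of
the three per-event differences. Button presses are taken from the EMG
unit's event channel as exact timestamps, not detected from signal.
"First time the coordinate reaches its maximum" is read as the apex of
each of the three gesture repetitions, not a global maximum — three
repetitions require three events. The skeleton's vertical axis, the
hand-raise axis, and the anterior COP column are declared once in the
session manifest rather than hard-coded, since device frames vary.

Measured on 20 synthetic sessions with true offsets drawn uniformly from
[−1, 1] s, recovered-offset RMSE is ≈ 1 ms for the EMG pair and ≈ 6 ms
for the COP pair (the COP pair is limited by the 30 Hz head stream and
100 Hz board noise).

## Segmentation and exclusion

Each stand-up epoch runs from the **sitting instant** — a local minimum
of pelvis height — to the subsequent **standing instant** — a maximum of
head height. Both traces are smoothed (~150 ms window) before extremum
search; missing frames are bridged by interpolation *for extremum search
only*. Pelvis minima use the prominence machinery (three deep, widely
separated valleys per block). Head maxima cannot: against the terminal
standing plateau a small extension overshoot has near-zero topographic
prominence, so the standing instant is the *interior argmax* of head
height between consecutive sitting instants (with parabolic refinement),
and a boundary argmax raises an error naming the monotone trace. The
extremum search is applied per repetition within each manifest-declared
block window, not per recording: each block holds three sit minima, so a
global extremum would find only one.

An epoch is **excluded** when the fraction of its native-rate camera
frames with *every* joint missing is ≥ 0.5. The threshold is inclusive —
"half of the time" read conservatively — and frames with only some
joints missing count as present (feature code handles partial
missingness separately). Exclusion operates on camera frames, not on the
resampled 1000 Hz grid, because the rule counts sensor dropouts.

## Features

- **iEMG**: trapezoidal integral of the 0–100 envelope over the epoch,
  in %·s; additive over sample-aligned partitions to ~1e-9 relative.
- **max EMG**: largest envelope sample in the epoch.
- **Trunk flexion angle**: angle between the pelvis→neck segment and the
  world vertical-up unit vector, $\theta = \arccos(v_y/\|v\|)$ in
  degrees, clamped to [0, 180]. Invariant to yaw rotation and uniform
  scaling; frames missing pelvis or neck are skipped, not interpolated,
  and an epoch with no usable frame yields a missing feature with a
  warning.
- **Mean AP COP**: arithmetic mean of the anterior–posterior coordinate
  over the epoch, in board units (mm; negative = posterior). The board
  origin convention cancels in the within-subject jacket differences.

## Statistics

The battery (`run_sts_comparisons`) reproduces the study design's
comparisons from the pooled feature table: left-vs-right paired t per
condition for iEMG and max EMG (6 tests), jacket-vs-none paired t for
each of the four features per condition (12 tests, reported unadjusted),
one-way repeated-measures ANOVAs across the three conditions for iEMG and
max EMG (2 tests), and the three pairwise condition comparisons of
maximum trunk angle with Benjamini–Hochberg correction applied to exactly
that three-test family (3 tests) — 23 labeled results.

Design choices made where the design was genuinely open:

- **Analysis unit**: per-subject means over the three repetitions
  (n = subjects), the default; pooling 30 epochs as independent would
  pseudo-replicate. `unit = "epoch"` pairs individual repetitions
  instead.
- **Laterality**: bilateral features enter condition/jacket comparisons
  as the left/right mean; the dedicated left-vs-right tests carry the
  asymmetry question.
- All t-tests are **two-sided**; no directional hypothesis is assumed.
- The ANOVA is **repeated-measures** (subject as error stratum), matching
  the within-subject design; `rm_anova` verifies the subject × condition
  table is complete and names missing cells.
- `z_transform` uses the population-sd convention by default
  (`sample_sd = TRUE` available); `time_normalize` maps an epoch onto
  100 equally spaced relative time points (n = 1 takes the midpoint).

## The synthetic generator

`generate_session()` emulates, on the skeleton (master) clock: three hand
raises at 3/6/9 s with exact button timestamps on the shifted EMG clock;
three toe stands at 13/16/19 s (head-height bumps plus forward COP
excursions); then six blocks of three repetitions. Per repetition,
pelvis and head heights follow smoothstep sit-down/stand-up transitions
between anthropometric plateaus. Two transients give each repetition the
unique extrema the segmentation rule assumes, chosen once as realistic
movement features: a 5 cm pelvic settling dip (σ = 0.12 s) at the
sitting instant (seat compression and pelvic rocking during the forward
lean) and a 4 cm head overshoot at the standing instant (terminal trunk
extension). EMG bursts are Gaussian-windowed (σ = 0.18 s) band-limited
noise — the carrier is pre-filtered to 5–30 Hz so burst energy lies in
the analysis band — with two activation peaks per rise in two-hand
conditions (initial lean, final extension) and one in the one-hand
condition. The jacket multiplies EMG burst amplitude (default × 1.5),
shifts the AP COP baseline (default −15 mm, posterior), and leaves the
trunk angle unchanged (default Δ = 0); the one-hand condition loads the
right side more (right/left amplitude ratio 1.25). Subject-level random
effects (amplitude, COP baseline, angle offset, body weight) and
repetition-level noise sit on top. Skeleton units are meters (y up), COP
units millimeters (y anterior) — conventions declared in the manifest,
since boards do not report calibrated units uniformly.

Identical `(config, seed)` pairs produce byte-identical sessions; the
subject stream is seeded from `(seed, subject_id)`.

**What it does not emulate**: soft-tissue artifact, electrode noise
spectra beyond white noise, postural sway structure, fatigue or learning
across repetitions, body-tracking failure modes other than
missing-at-random frames, and any forward dynamics. Passing recovery
tests on these signals therefore demonstrates the correctness of the
processing chain, not the field validity of the features on human
recordings.

`simulate_feature_cohort()` draws per-epoch feature rows from the same
effect structure without synthesizing raw signals. Calibration studies
that need thousands of cohorts (type-I error of all 23 tests over 1000
null cohorts; jacket-pattern recovery over 200 effect cohorts) run at
this level — raw-signal simulation at that replicate count is far beyond
desk scale — while the raw-signal path is validated separately on tens
of sessions (offset recovery over 20 sessions, boundary recovery over
216 epochs, feature recovery against ground truth per session).

## Verification problem sizes and tolerances

The test suite and `scripts/acceptance.R` use: 100 random instances per
brute-force oracle (moving average vs a double loop, exact to 1e-12;
iEMG vs 10× resolution quadrature, 1e-6 relative; paired t vs the closed
form and BH vs the min-over-suffix definition, 1e-10/1e-12;
repeated-measures F vs an explicit sum-of-squares decomposition, 1e-9);
20 sessions for offset RMSE (bounds 5 ms EMG, 15 ms COP); one noiseless
session (boundaries exact to the frame) plus 12 sessions at 5 mm
kinematic noise — 1 % of the 0.5 m pelvis rise — for 216-epoch boundary
recovery (≤ 2 frames in ≥ 95 %); and the cohort counts above for
calibration (each test's type-I rate within [0.03, 0.07] at α = 0.05)
and effect recovery (full qualitative jacket pattern — iEMG up and COP
posterior in all three conditions, angle null — in ≥ 80 % of cohorts).

## Known limitations

- Offsets are modeled as constants per stream pair; clock drift within a
  session is out of scope.
- Linear interpolation slightly attenuates extrema of signals with
  energy near the source Nyquist rate; irrelevant for slow kinematics,
  but not a general resampler.
- The 5–30 Hz analysis band is unusually low for surface EMG (typical
  envelope pipelines band-pass 20–450 Hz before rectification); it is
  kept as the package default deliberately and is fully configurable via
  `emg_config()`.
- Min–max scaling ties the EMG scale to each recording's own extremes;
  absolute amplitudes are not comparable across sessions, only
  within-recording contrasts are.
- The sit-down phase and STS sub-phases (flexion momentum, lift-off) are
  not segmented.
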