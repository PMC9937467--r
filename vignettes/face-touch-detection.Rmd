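---
title: "Detecting face touches from a wrist-worn IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting face touches from a wrist-worn IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetouch)
```

## The problem

Hand-to-face contact is a major route for surface-mediated transmission of
respiratory infections, and it is frequent enough (tens of touches per hour)
that people cannot reliably police it themselves.  A wrist-worn inertial
measurement unit (IMU) — the sensor already inside every smartwatch — sees
the arm kinematics of a face touch: a reach that rotates the forearm, a
short dwell at the face, and a return.  `facetouch` implements a complete
detection pipeline for such recordings: template matching with dynamic time
warping (DTW) over a sliding window, followed by k-nearest-neighbour (KNN)
classification of the per-window DTW scores, and event-level evaluation.

The pipeline operates on tri-axial acceleration (m/s²) and angular velocity
(deg/s) sampled at 128 Hz, in two settings: *controlled* trials (scripted
repetitions of face touching and of five confounding gestures — eating,
drinking, head scratching, handwashing, reaching/picking) and *natural*
trials (free daily activity, with face touches noted on a self-reported log
sheet).

## Processing chain

1. **Filtering.** Each channel is low-pass filtered with a zero-phase
   Butterworth response, cut-off 30 Hz, to remove skin-motion artifact.
   "Zero-phase 6th order" is interpreted the way biomechanics pipelines
   conventionally build it: an order-3 design run forward and backward
   (`filter_order = 3`), which doubles the effective order and cancels the
   phase.  An order-6 design run twice is available for sensitivity
   analysis.  The implementation uses steady-state initial conditions plus
   odd-reflection padding, so a constant channel passes through bit-exactly
   (unit DC gain) — a property the tests assert at 1e-9.

2. **Vertical alignment.** The accelerometer mean over the 10-s quiet rest
   window that opens a subject's first trial estimates the gravity
   direction in the sensor frame.  The recording is rotated by the minimal
   (geodesic) rotation taking that direction to (0, 0, 1): axis
   $g \times z$, angle $\arccos(g \cdot z)$, Rodrigues form; the
   anti-parallel case falls back to a 180° rotation about the sensor x
   axis.  Tilt is thereby normalized across subjects while heading about
   the vertical — unobservable from an accelerometer — remains arbitrary.
   One rotation is estimated per participant (from the first trial) and
   applied to all of that participant's trials.

3. **Down-sampling and quantization.** Signals are decimated 128 → 32 Hz by
   keeping every 4th sample.  Decimating a 30 Hz-bandwidth signal to 32 Hz
   aliases content above 16 Hz; the default replicates that published
   choice, with an opt-in 12 Hz anti-alias filter (`antialias = TRUE`).
   Channels are then quantized to integer levels,
   `level = round(value/step)` with ties away from zero.  The steps —
   0.5 m/s² for acceleration, 5 deg/s for angular velocity — are this
   package's choice (the original values are unpublished), sized so typical
   gesture dynamics span roughly ±40 levels; both are configurable.
   Quantization keeps DTW local costs integral, so scores accumulate
   without floating-point error.

4. **Labeling.** Controlled trials take per-sample labels straight from the
   script (1 face touch, 2 confounding, 0 other; boundary samples of
   touching events go to the earlier event).  Natural trials are labeled
   from the log sheet: around each noted instant the smoothed magnitude of
   the angular velocity is searched for the face-touch signature — two
   movement lobes bracketing a quiet dwell.  See "refinement rule" below.

5. **Template scoring.** One face-touch repetition, preprocessed through
   the full chain, is the template (by default the first face touch of the
   first subject's controlled trial; per-subject overrides are supported).
   Every 3-s window (96 samples), advanced by 6 samples (0.1875 s — the
   integer-grid rendering of a 0.2-s step at 32 Hz), is scored against the
   corresponding template channel with FastDTW.  Each of the six channels
   is scored independently; there is no joint multivariate DTW and no
   length normalization of scores.

6. **Features and classification.** Each window position ("instant")
   carries an 8-D feature vector: the three acceleration-channel scores,
   the three gyroscope-channel scores, and the two within-modality means.
   The means are exact linear functions of the first six coordinates and
   are asserted as such.  An instant inherits the label of the sample at
   its window centre (a `"majority"` rule is available).  KNN with
   Euclidean distance and majority voting classifies instants, for every
   odd k in 3..21; instants are split 70/30 into train/test after seeded
   shuffling, controlled and natural pooled separately.  No feature
   standardization is applied — all eight features share the DTW-score
   scale.

7. **Evaluation.** The unit of analysis is the event.  Predicted-positive
   instants merge into predicted events (gaps ≤ 0.4 s bridged; each event
   spans first window start to last window end; overlapping extents are
   unioned; events shorter than 0.5 s dropped).  A true face touch
   overlapped by any prediction is a TP — counted once however many
   predictions cover it; a prediction overlapping no true touch is an FP;
   a scored negative event (confounding gesture) untouched by predictions
   is a TN.  Metrics: sensitivity TP/(TP+FN), precision TP/(TP+FP),
   FPR FP/(FP+TN), FDR FP/(FP+TP), accuracy (TP+TN)/(RP+RN), all reported
   as integer percent with ties rounded up.  In natural trials only face
   touches are labeled, so no negatives are scored: TN/FPR/FDR are omitted
   and accuracy reduces to TP/RP.

## DTW and the FastDTW approximation

Exact DTW fills the full cost matrix with local cost $|a_i - b_j|$, the
symmetric step pattern (match/insert/delete, each weight 1) and
boundary-anchored paths; the score is the minimal cumulative cost.  FastDTW
coarsens both series by pairwise averaging (an odd tail sample is carried
through), solves the coarse problem recursively, projects the coarse path
onto the fine grid, widens it by `radius` cells, and runs the constrained
DP inside that corridor; series shorter than `radius + 2` are solved
exactly.  Because the result is the cost of a *valid* path, it can never
undercut the exact score, and it equals it whenever the radius spans the
matrix — both properties are exercised on hundreds of random quantized
pairs in the test suite.  The default radius is 1, the canonical setting of
the reference algorithm.

## The log-sheet refinement rule

The natural-environment labels come from approximate self-reports, off by
up to a couple of seconds.  The documented recovery idea — find the minimum
of the smoothed angular-velocity magnitude near the noted instant, then
take the flanking maxima as the touch boundaries — fails on realistic
signals in one specific way: rest is exactly as quiet as the dwell, so the
global minimum of a ±5-s search window routinely falls in the rest gap
*next to* the touch rather than in the dwell, bracketing a rest period
instead of the gesture.  The package therefore inverts the search order:
it finds prominent local maxima (prominence ≥ 10 deg/s) in the window,
forms candidate pairs of *consecutive* peaks no more than `max_span_s`
(default 3 s) apart — a plausible touch duration, while peak pairs
bracketing a rest gap are farther apart — and picks the pair closest to
the noted instant; the dwell valley is the interior minimum of that pair.
This satisfies the same boundary-bracketing contract (start < valley <
end), is robust to ±2 s of log jitter (the suite requires ≥ 95% recovery
of 200 jittered synthetic gestures), and degrades to a flagged-for-review error when no qualifying pair exists.
Entries that fail refinement are skipped and reported by the pipeline, not
silently dropped.

Refined boundaries sit at the gyro-magnitude peaks, which by construction
lie *inside* the true contact interval — an under-segmentation.  This is
harmless downstream because event matching is overlap-based.

## The synthetic cohort

No recordings are distributed with the detection problem, so the package
ships a seeded generator that emulates the study conditions and makes every
stage testable end to end:

* **Kinematics.** A gesture is a minimum-jerk rotation (position profile
  $10\tau^3 - 15\tau^4 + 6\tau^5$) of the wrist about a class-specific
  axis: reach, dwell, return.  The gyroscope is the analytic derivative —
  two lobes around a quiet dwell, the signature the labeling stage needs;
  the accelerometer sees sensor-frame gravity rotated along the orientation
  trajectory, plus the second derivative of a minimum-jerk reach
  displacement (0.25–0.45 m scaled by excursion), plus white Gaussian noise
  (0.05 m/s², 1 deg/s).
* **Classes.** Face touch: 2.2–3.2 s, 70–95° excursion, 30% dwell.
  Confounders differ in excursion, duration, dwell, axis mix and
  oscillation: drinking (longer dwell), eating (2–3 repeated small cycles),
  head scratching (oscillatory dwell, 3–4.5 Hz), handwashing (sustained
  2–4 Hz oscillation, low excursion), reaching/picking (opposite-signed
  excursion, brief dwell).  These values are the package's own "realistic"
  choices; they were fixed once, before any end-to-end measurement, and are
  deliberately not tuned.
* **Sessions and cohort.** Sessions open and close with 10 s of rest.
  Controlled sessions script 25 repetitions of the face touch and of each
  confounder with 2.5–4.5-s gaps (≈ 18–20 min); natural sessions are
  20 min with 5 face touches and 2 of each confounder placed into random
  rest gaps (≥ 3 s), and a log sheet holding each touch midpoint jittered
  by ±2 s.  Eleven subjects by default; each draws duration/excursion
  offsets within ±20% and a band-mounting rotation (roll about the forearm
  axis plus ≤ 15° tilt) once.  Everything derives from a single seed; the
  same seed reproduces the cohort bit for bit.

What the generator does *not* emulate — and what green tests therefore do
not certify about real data: postural drift and non-gesture arm activity
during "rest", within-gesture pauses, sensor bias/scale error, magnetic or
temperature effects, and genuinely idiosyncratic movement styles.  Synthetic
separability is better than real-world separability; the end-to-end
criterion (≥ 80% event-level sensitivity and precision at k = 3) is a
regression property of the pipeline, not a claim about human data.

## Evaluating on a randomized instant split

Randomizing *instants* (not subjects, not events) into 70/30 replicates the
published protocol, including its known optimism: temporally adjacent
windows of one gesture can land in both sets.  A subject-blocked split
exists behind `split mode` in the classify module but is off by default to
stay faithful; LOSO cross-validation is the principled alternative and is
reported alongside.  How scattered test-set instants were merged into
"periods" in the original evaluation is unstated; this package merges the
positive test instants of one session with the same gap rule as on the
full grid, and counts as condition-positive (RP) exactly the truth events
containing at least one test-set window centre ("exposed" events, RN alike
for negatives).  With ~30% of a 16-instant event in the test set, an event
escapes exposure with probability well under 1%.

## Numerical and tie-break conventions

* KNN ties: plurality first; then the smaller summed Euclidean distance
  among tied classes; then the class of the single nearest neighbour.
  Neighbour order itself breaks distance ties by training index, so
  predictions are fully deterministic (and match a brute-force oracle
  exactly in the tests).
* Train size is `round(0.7 n)` with half-up rounding; R's
  round-half-to-even would make the split size parity-dependent.
* Percent metrics round half *up* (91.5 → 92), matching how the benchmark
  tables print; an undefined metric (zero denominator) is `NA`, never 0.
* The controlled-environment benchmark table in `inst/extdata` carries
  `RN = 412`, which is not printed anywhere: it is the unique count of
  scored negatives consistent with all ten printed accuracy rows under
  half-up rounding, and it is labeled as inferred.
* DTW backtracking prefers diagonal, then row, then column steps; the
  FastDTW corridor always contains the projected coarse path, so the
  constrained DP is always feasible.

## Problem sizes

The default cohort (11 subjects, ≈ 18–20 min per session, two sessions
each) yields roughly 64k controlled and 70k natural instants — the same
order as the published bookkeeping (~83k and ~67k).  One full experiment
(preprocess, score, 70/30 sweep over ten k values, LOSO over 22 folds)
runs in a few minutes on one core; the unit-test suite uses 2–3-subject
cohorts with shortened sessions except for the one end-to-end acceptance
check, which runs the full default cohort.

## Known limitations

* Heading about the vertical is not normalized (it cannot be, from an
  accelerometer alone), so cross-subject channel mixing survives
  alignment; the instant-level split absorbs this, LOSO feels it.
* The template is one exemplar from one subject; per-subject templates are
  supported but not the default.
* `instants_to_events` merges predicted events whose 3-s extents overlap,
  which makes the effective merge gap `max(merge_gap_s, window_s)` on
  dense grids; on the sparse 30% test grid the distinction matters and the
  0.4-s gap rule is the binding one.
* The generator's rest is pure gravity plus noise; real "other" activity
  is more adversarial for precision.
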