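---
title: "Methods: pose-based gait features, stress markers and waveform statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose-based gait features, stress markers and waveform statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstress)
```

`gaitstress` implements a complete analysis chain for a between-groups
treadmill study asking whether a measurement procedure (marker-based optical
motion capture, with minimal clothing and examiner contact) induces
psychosocial stress and alters gait. Gait is observed only through 2D
pose-estimation keypoints from sagittal video; stress is observed through
salivary cortisol and two questionnaires. This vignette documents the models,
conventions, parameter choices and known limitations; the README shows a
worked end-to-end example.

## Gait processing chain

**Input.** A trial is a `keypoint_series`: per-frame image coordinates and
confidences of 17 COCO-layout keypoints at 50 Hz. Missing detections
(confidence 0) are never interpolated; frames carrying them are flagged and
any stride containing a flagged frame is dropped later. Interpolation would
invent data exactly where pose estimators fail (occlusion), which is also
where clothing-related bias lives.

**Filtering and trimming.** Trajectories are low-pass filtered with a
second-order Butterworth design at 10 Hz, applied forward-backward. The paper
convention for such filters leaves phase handling unstated; we use zero-phase
application because event *timing* is the quantity of interest downstream and
a one-pass filter would delay every event by several frames. The
forward-backward pass squares the magnitude response (effectively
fourth-order attenuation); this is recorded here so users comparing against a
one-pass implementation know why attenuation differs. Reflection padding
suppresses the start/end transients. The first 30 s of each trial are then
discarded as treadmill familiarization. The order (filter, then trim) avoids
filter transients inside the analysis window; the alternative order differs
only near the cut and was not used.

**Heel strikes.** Left heel strikes are defined as the frame *following* the
maximum of the left ankle-hip image-plane distance (one frame = 0.02 s at
50 Hz), the offset that aligns keypoint events with force-plate onsets. Two
geometric facts shape the implementation. First, for a hip-knee-ankle chain
the distance depends only on the knee angle
(`d^2 = L_t^2 + L_s^2 + 2 L_t L_s cos(knee)`), so the distance peaks where
the knee is straightest. Second, `cos` is flat near full extension, so the
peak sits on a broad plateau where pixel noise spawns spurious local maxima.
The detector therefore finds peaks on a stride-scale smoothed copy of the
distance (centered moving average, 15% of the dominant period, the dominant
period coming from the discrete Fourier peak of the signal), then refines
each peak to the raw-signal argmax inside the smoothing window. On noiseless
data the refinement recovers the exact maximum; on noisy data the peak
*count* is robust while the peak *location* wobbles a few frames, which is
visible as a small stride-time jitter but leaves stride-averaged waveforms
nearly unbiased. Candidate peaks closer than half the dominant period are
pruned (higher peak wins); maxima within half a period of the trial edges are
discarded because a genuine cycle peak cannot be verified there. Plateau ties
resolve to the first frame, then the +1 offset is applied.

**Strides.** Consecutive events delimit strides; each stride is linearly
resampled to 101 nodes (0-100% of the cycle). Stride durations outside
0.4-2.5 s are dropped (configurable) as detection glitches, with a count kept
in the run log.

**Joint angles.** Segment angles are measured from the downward vertical in
image coordinates (y down), positive toward the walking direction. The
default walking direction is toward image left (`forward = "-x"`),
configurable per trial. Conventions: hip flexion = thigh minus trunk angle
(thigh forward of trunk positive); knee flexion = thigh minus shank (0 at a
straight leg); shoulder flexion = upper arm minus trunk; elbow flexion =
forearm minus upper arm (0 = fully extended, so the interior elbow angle is
180 minus the stored value); arm swing = the whole-arm (shoulder-wrist)
vector's angle from the downward vertical. The conventions are attached to
every `joint_angles()` result so an alternative convention is a documented
transform away. Strides in which the interior elbow angle dips below 80
degrees are removed from all arm signals (the hand was likely at the head,
not swinging); leg signals are untouched.

**Discrete features.** Stride time; per-signal waveform variability as
\[
  cv = \frac{\sqrt{\frac{1}{N}\sum_{i=1}^{N}\sigma_i^2}}
            {\frac{1}{N}\sum_{i=1}^{N}\lvert X_i \rvert}, \qquad N = 101,
\]
with \(\sigma_i\), \(X_i\) the across-stride sample standard deviation
(denominator M-1; the source convention is unstated and the sample form is
the conservative choice) and mean at node i; and upper-body ranges of motion
(per-stride max minus min, averaged over strides). Features are averaged over
the two walking bouts per participant.

## Stress markers

**Cortisol.** Six samples S0-S5 (nmol/L). S1-S5 are baseline-adjusted by
subtracting S0; the maximum increase over baseline is kept absolutely and as
a percentage of S0 (undefined when S0 = 0, flagged rather than imputed). A
participant is a *responder* when the maximum increase strictly exceeds
1.5 nmol/L ("exceeds" read as a strict inequality).

**Questionnaires.** PANAS (20 items, 10 positive / 10 negative affect) and
SSSQ (24 items, six dimensions) on 5-point Likert scales. Scores are item
means on the 1-5 scale, matching the instruments' reporting range, with item
sums attached as metadata. Item-to-subscale keys ship as editable YAML
(`inst/extdata/*_key.yaml`) with reverse-keying support; the default PANAS
key is the standard published ordering, while the default SSSQ key assigns
consecutive blocks of four items per dimension because the exact
translated key is instrument-version specific. Analyses that only compare
scores across timepoints and groups are unaffected by which items form a
block, but users scoring real SSSQ data should install their instrument's
key. The SSSQ total is the mean over all 24 items (not the mean of dimension
scores; with the default equal-size key the two coincide).

## Statistics

**Mixed ANOVA.** Split-plot decomposition with group (between) and sample/
timepoint (within): the group effect is tested against subject-within-group
error, the within and interaction effects against the subject-by-within
residual. Sums of squares are sequential (group, then within, then
interaction), which coincides with the classical decomposition for balanced
groups and handles the 19/20 split of a typical cohort. Partial eta squared
is `SS_effect / (SS_effect + SS_error)`. Greenhouse-Geisser epsilon is
estimated from the double-centered pooled within-subject covariance and the
epsilon-corrected p-value is reported alongside the uncorrected one, since
sphericity rarely holds for ordered saliva samples. Degenerate inputs: zero
error variance with a zero effect gives F = 0 (constant data); zero error
variance under a positive effect is an error, not an infinite F.

**Pairwise tests.** Shapiro-Wilk at alpha = 0.05 on each sample (and on the
differences when paired) gates between a t-test (Welch by default for two
samples; the pooled form is a flag) and the Wilcoxon analogue. p-values are
Bonferroni-corrected within a feature group: `min(1, m * p)`. Hedges' g
(`J = 1 - 3/(4(n_a+n_b-2)-1)`) accompanies parametric comparisons.

**SPM over the stride.** For hip and knee waveforms, each participant
contributes one mean waveform; a node-wise two-sample t field (pooled
variance) is thresholded at the random-field-theory critical value for the
field's estimated smoothness. Smoothness (FWHM) comes from the gradients of
the normalized residuals; the threshold solves
`alpha = 1 - exp(-E[EC])` with the 1D Euler-characteristic densities of a t
field, two-sided via alpha/2 per tail. Suprathreshold clusters are reported
as percent-of-stride intervals with direction. A permutation threshold (the
95th percentile of the max-|t| distribution over group-label permutations,
exhaustive when at most 20,000 assignments exist, otherwise 10,000 seeded
draws) is attached as a cross-check; for smooth fields at moderate n the two
agree within a few percent. With very small groups the permutation
resolution is flagged, and at tiny degrees of freedom the RFT threshold may
be infinite (no finite value attains the level), reported honestly as "no
attainable cluster".

## The synthetic cohort

The generator exists so every stage can be tested against known truth
without any data download. Its defaults are the study conditions: 50 Hz
video, 1000 Hz ground reaction forces, 240 s bouts (first 30 s trimmed), two
bouts (slow/fast) per participant, 19 + 20 participants, six cortisol
samples, questionnaires at Q-pre/Q-post plus Q-marker for the OMC group
only, and 2 px keypoint noise, a typical jitter level for video pose
estimation. Tests and the acceptance script state smaller durations and
cohort sizes explicitly where full-size runs would add nothing but time.

**Walker.** A planar kinematic chain driven by truncated Fourier joint-angle
waveforms (defaults resemble normative treadmill gait: hip -10..30 deg
single-peaked, knee double-bumped with ~56 deg swing flexion, arms anti-phase
with the ipsilateral leg, elbow interior angle held well above the 80 deg
exclusion). The hip oscillates vertically at stride frequency; the right side
runs half a cycle out of phase. One deliberate departure from normative gait:
stance-phase knee flexion stays near 29 deg rather than dipping to ~5 deg, so
that the ankle-hip distance has a single dominant peak per stride. With two
near-equal extension events per cycle the heel-strike rule is ill-posed under
noise for *any* detector -- the generator makes the detection problem
well-posed and lets tests measure the pipeline rather than an ambiguity of
the construction. Truth records the heel-strike frames (the discrete argmax
of the pre-noise sampled distance, so noiseless detection must match
bit-for-bit), the 101-node waveforms laid out from one frame after the
distance maximum (exactly how the pipeline segments strides, with left-arm
signals half a cycle out of phase), the stride time and the arm-swing ROM.
Gaussian pixel noise and constant per-keypoint "clothing bias" offsets are
added last; per-stride amplitude jitter generates genuine stride-to-stride
variability so cv is nonzero. GRF is a double-bump profile over the first
60% of each cycle (stance), used only as an independent event oracle.

**Cortisol.** Baseline plus a gamma-shaped pulse peaking 17 min (default)
after onset -- inside the physiological 15-20 min delay -- with an
exponential-like tail; optional lognormal measurement noise. Sampling clocks
follow the protocol narrative: the OMC group's S1 comes ~40 min after
arrival (changing + 20-30 min marker application), controls proceed directly
to walking so their S0-S1 gap is short; S4 = S3 + 15 min, S5 = S4 + 10 min.
Amplitudes are drawn per group (OMC larger and more variable), reproducing a
mean maximum increase near the responder threshold for OMC and well below it
for controls.

**Questionnaires.** Item responses are rounded, clipped latent normals
around per-timepoint subscale means; defaults encode the marker-application
signature (negative affect up, positive affect down at Q-marker, recovery at
Q-post) and mild SSSQ decreases.

**What passing tests do and do not show.** The generator's keypoints are
exactly a planar chain plus i.i.d. Gaussian noise and constant offsets. Real
pose estimation errors are autocorrelated, heteroscedastic (worse at
occlusion), and clothing bias is posture-dependent rather than constant; real
gait has between-stride timing variability that the generator only mimics
through amplitude jitter. Recovery tests therefore validate the *pipeline's
correctness*, not the field accuracy of 2D pose estimation, which published
comparisons put at ~4-6 deg mean absolute error for hip and knee.

## Numerical choices

* Stride resampling is linear interpolation; at 101 nodes the ROM bias on a
  one-cycle sinusoid is below 0.1%.
* Peak plateaus resolve deterministically to their first frame.
* GRF events: 20 N rising-edge threshold, 50 ms-scale debounce (0.3 s
  default), belt crossover flagged but not corrected.
* The cv denominator uses the mean *absolute* node mean; an all-zero mean
  waveform is an error, not a NaN.
* Permutation enumeration switches to seeded sampling above 20,000
  assignments; enumeration is seed-free, so tiny-group results are exactly
  reproducible.
* All simulation entry points take an explicit seed and restore the caller's
  RNG state.

## Limitations

Only left-side sagittal kinematics are computed (right-side events and
angles would mirror trivially but are not emitted); toe-off and spatial
parameters are out of scope; the mixed ANOVA requires complete within-data
(no imputation); Bonferroni is the only correction offered; and the
reproduction of the original study's numbers requires its deposited dataset,
which this package does not download -- the file readers accept the same
formats so such an analysis is a configuration, not a code change.
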