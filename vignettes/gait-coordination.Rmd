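---
title: "Quantifying hip-knee coordination from wearable IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hip-knee coordination from wearable IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(gaitcoord)
library(dplyr)
```

## The scientific question

People with Parkinson's disease (PD) often walk with a more rigid,
less adaptable gait than healthy older adults (HOA). One way to quantify
this is *inter-joint coordination*: how the hip and knee move relative to
each other over the gait cycle, and how variable that relationship is from
stride to stride. `gaitcoord` implements the full measurement chain from
raw body-worn inertial sensors (pelvis, right thigh, right shank) to
group-level statistics, together with a calibrated synthetic cohort
generator that provides known ground truth for validation.

## The measurement model, stage by stage

### Sensors to joint angles

Each IMU provides tri-axial acceleration (m/s^2), angular velocity (rad/s)
and magnetic field (microtesla) at 200 Hz. All channels pass through a
zero-phase 4th-order low-pass Butterworth filter at 6 Hz
(`lowpass_filter()`); walking kinematics live well below 6 Hz and the
forward-backward application avoids the group delay of a causal filter,
which would otherwise bias the phase analysis downstream. The quoted order
is the designed order of each pass; two passes double the effective order
and place the -6 dB point of the cascade at the nominal cutoff. Whether
zero-phase filtering is appropriate is a genuine design choice: we default
to it (`zero_phase = TRUE`) precisely because the core outcome is a timing
measure.

Orientation comes from a complementary filter (`complementary_fuse()`):
gyroscope integration blended each sample with the TRIAD attitude implied
by the accelerometer (gravity) and magnetometer (heading). The blending
gain is the correction weight per sample; the default 0.02 (98% gyroscope
weight) is a conventional choice for walking -- large enough to bound drift
over a multi-second pass, small enough that step impacts do not contaminate
the attitude. Quaternions are scalar-first, Hamilton convention,
sensor-to-world; both conventions are stated explicitly because published
pipelines differ and silent mismatches flip rotation signs.

Joint rotation is the proximal-conjugate product
`q_joint = conj(q_prox) * q_dist`, decomposed in the intrinsic Z-Y-X
sequence with Z the medio-lateral axis; the Z angle, unwrapped over time,
is the sagittal joint angle (flexion positive under the documented mounting
convention). An optional quiet-standing window
(`compute_joint_angles(calibration_window_s = )`) removes constant mounting
offsets; it defaults to off because the synthetic cohort has no standing
phase and constant offsets cancel in every downstream quantity (excursion
is a range; the phase analysis centers its input).

### Gait events and cycles

Initial contacts (IC) are detected on the sagittal shank angular velocity:
mid-swing peaks are local maxima above 0.5 rad/s (the signal peaks at
several rad/s during swing, so the threshold is not delicate), and each IC
is the first negative-going zero-crossing after its peak. The
negative-going direction corresponds to mid-swing angular velocity being
positive under our sign convention; a `convention` flag handles recordings
with the opposite sign. Where automatic events are judged wrong, an
events-override CSV replaces them per pass (the manual-adjustment hook).
Cycles span consecutive ICs, are gated to physiological durations
(0.4-2.5 s) in place of visual inspection, and are linearly interpolated
onto 101 points (0-100% of the gait cycle). Linear interpolation is exact
for the piecewise-linear features that matter here and introduces no
overshoot.

### Continuous relative phase

Each joint's instantaneous phase comes from the analytic signal: the angle
series is centered by its midrange `(max + min)/2`, the Hilbert transform
computed by FFT, and the phase `atan2(imag, real)` unwrapped
(`hilbert_phase()`). Centering is essential -- an uncentered oscillation
yields a phase that never completes a cycle.

The Hilbert transform is nonlocal, so the ends of a finite window are
distorted. Inside the pipeline we use the natural remedy: each walking pass
carries one extra gait cycle before the first IC and after the last, the
transform runs on the whole pass, and only the span between first and last
IC is kept. For standalone signals `hilbert_phase(pad_n = )` synthesises a
pad by periodic continuation, with the dominant period estimated from the
first autocorrelation peak beyond the first zero crossing. We deliberately
do not mirror-pad: a mirrored extension has a derivative kink exactly at
the span boundary, and empirically that kink leaks several degrees of phase
error into the first half-second of signal, whereas a periodic
continuation of a cyclic signal is smooth at the junction. When the signal
is not convincingly cyclic (peak autocorrelation below 0.6) the transform
runs unpadded, which measurably beats any synthetic extension we tried on
non-periodic test signals such as chirps.

CRP is the absolute hip-knee phase difference folded to `[0, 180]`
degrees: 0 is in-phase, 180 anti-phase. Following the standard workflow,
CRP is computed once on the continuous pass and *then* segmented into
101-point cycles, rather than per cycle, so segmentation cannot
re-introduce edge artefacts.

Two scalars summarise each participant and speed:

* **MARP** (mean absolute relative phase): the mean over the 101 nodes of
  the across-cycle ensemble mean CRP curve -- the average coordination
  strategy.
* **DP** (deviation phase): the mean over the nodes of the across-cycle
  sample SD (n-1 denominator; the convention is stated because with a
  handful of cycles the denominator visibly matters) -- the coordination
  variability.

Both are also kept as 101-point curves (ensemble mean and SD), because the
waveform-level group comparison operates on the curves while the
scalar-level models operate on MARP/DP; the package emits both and leaves
the choice of representation to the analyst.

### Group statistics

Participant screening uses Tukey fences (1.5 x IQR, type-7 quartiles) per
group on the preferred-speed condition, by default on MARP and DP; a
participant outside any fence is excluded from all conditions, and the
exclusion log records who and why. The screened metrics are configurable
since outlier screens in gait studies rarely state them.

Walking speed is analysed with a two-way ANOVA (group x speed condition)
on observations pooled across participants, with type-III sums of squares
and sum-to-zero contrasts (the SPSS-compatible convention) and Bonferroni
post hocs for significant main effects. The pooled fixed-effects model
reproduces the denominator degrees of freedom conventionally reported for
this design; it ignores the repeated-measures structure, which we flag as
a caveat -- a mixed model would be the stricter choice but changes the
reported df pattern.

MARP, DP and the joint excursions are analysed with two-way ANCOVAs using
actual walking speed as the covariate (the generator emits true speed; a
field pipeline would supply measured speed). The interaction is tested
first; simple main effects are only computed when it is significant,
otherwise post hocs address significant main effects. Effect sizes are
partial eta squared.

The waveform-level comparison is one-dimensional statistical parametric
mapping by permutation: pointwise pooled-variance two-sample t over the
101 nodes, with the family-wise critical threshold `t*` taken as the
`ceiling((1-alpha) n_perm)`-th order statistic of the max-|t| distribution
over random label permutations (observed labelling always included, so the
test is exact at level `floor(alpha n_perm)/n_perm`). Runs of nodes with
`|t| > t*` form supra-threshold clusters. We implement the permutation
variant only; random-field-theory thresholds are out of scope. Nodes where
both groups are degenerate (zero variance) fall back to an epsilon-floored
pooled SD (1e-8 of the response scale) so a genuine mean difference still
registers rather than dividing by zero.

## The synthetic cohort: what it emulates and what it does not

The generator (`simulate_cohort()`) draws participants whose walking
speeds and hip/knee excursions follow published group statistics for PD
and HOA cohorts at slow, preferred and fast speeds (the shipped YAML
defaults; e.g. PD slow speed 0.65 +/- 0.17 m/s, HOA preferred hip
excursion 40.5 +/- 7.6 degrees). Within a pass, joint angles are sinusoids
at the stride frequency; the knee lags the hip by a per-cycle draw from
`Normal(lag mean, lag SD)`, cross-faded over 5% of the cycle at each
boundary so the phase track stays smooth. This makes the CRP analytically
predictable: the true lag *is* the expected CRP, the lag SD *is* the
generative analogue of DP, which is exactly what parameter-recovery tests
need. Each participant additionally carries a habitual mean lag drawn with
a between-participant SD (default 7 degrees); without it every simulated
participant in a group would share one coordination strategy, MARP would
vary only through cycle-sampling noise, and group comparisons would come
out implausibly significant. Default lag parameters (HOA 55 +/- 8, PD
60 +/- 10 degrees, trial-to-trial) mirror the direction of reported group
trends (slightly more anti-phase, more variable coordination in PD)
without asserting significance.

Values that no table provides were fixed once at field-typical magnitudes:
cadence 96/110/124 steps per minute across the three speeds, postural
offsets of 5 degrees (hip) and 25 degrees (knee), sensor noise SDs of
0.05 m/s^2, 0.005 rad/s and 0.3 microtesla, ten passes per speed, and
cycles per pass derived from the published step counts (two steps per
right-sided gait cycle, minimum two cycles). The cycle period is snapped
to the sample grid so every true IC lies exactly on a sample, which lets
event-detection tests demand exactness rather than tolerance.

The shank angular-velocity channel is constructed, not derived from the
joint kinematics: one dominant positive mid-swing peak per cycle (at 75%
of the cycle, peak height scaled with walking speed) and a negative-going
zero exactly at each IC, tapered to zero outside the walking bout so the
lead-in/out cycles add no spurious peaks. The raw-IMU emission places the
implied segment orientations (pure sagittal rotations, level pelvis) into
a world frame with Y vertical, reads gravity and a fixed magnetic field in
each sensor frame, differentiates the orientation for the gyroscope, adds
noise, and clips at the emulated hardware ranges (+/-16 g, +/-2000 deg/s,
+/-1.9 Gauss).

What the generator does **not** emulate -- and therefore what passing
tests cannot certify about field data: soft-tissue artefact, magnetic
disturbance indoors, non-sinusoidal angle waveforms (real knees have a
double flexion bump), freezing of gait and tremor, left-right asymmetry,
and any frontal/transverse-plane motion. Validation against this generator
establishes that the pipeline's mathematics is correct, not that the
complementary filter gain or event thresholds are optimal for every
clinical recording.

## Numerical choices and degenerate inputs

* Butterworth filtering wraps `signal::butter` coefficients with
  odd-reflection padding and deviation-from-first-sample state handling,
  so a constant signal passes through exactly and startup transients decay
  inside the pad.
* Quaternion continuity is enforced (no sign flips between consecutive
  samples); unit norm is preserved to 1e-9 through every operation.
* Gimbal proximity (|Y| within 1 degree of 90) warns but retains values.
* A constant angle series has no phase: hard error naming the joint.
* A single CRP cycle leaves DP as `NA` with a warning; an empty cycle set
  is an error where a summary is demanded and an empty table otherwise.
* All-equal screening values have zero IQR; nobody is excluded because the
  fences require strict exceedance.
* Permutation SPM warns below 100 permutations and below 3 subjects per
  group; with the observed labelling included, the attained level is
  `floor(alpha n_perm)/n_perm`.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run, by design, at desk scale:
10-second analytic signals at 200 Hz; 200 gait cycles for MARP/DP
recovery; cohorts of 50 participants per group for generator calibration;
500 replicates x 200 permutations for the SPM family-wise-error check; and
500-replicate null simulations for the ANCOVA interaction type-I rate.
These sizes put Monte-Carlo error comfortably inside the asserted bands
while keeping a full run in the low minutes on one core.

## A worked example

```{r example, eval = FALSE}
spec_pd <- default_cohort_spec("pd")
spec_hoa <- default_cohort_spec("hoa")
cfg <- run_config(mode = "synthetic", seed = 42, out_dir = "gait_report")
res <- run_pipeline(cfg)
res$analysis$summaries
glance(res$stats$ancovas$marp)
autoplot(res$stats$spm$`preferred.crp_mean_deg`)
```

## Known limitations

The pooled-observation ANOVA/ANCOVA df convention, the single-sided
(right leg) analysis, the fixed world magnetic-field reference in the
fusion (a heading offset common to all sensors cancels in relative
orientation, a sensor-specific disturbance does not), and the sinusoidal
waveform family of the generator are the main simplifications. The
Friedman / Kendall's W branch sometimes quoted alongside this battery is
not implemented.
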