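---
title: "Methods: swing kinematics, pelvis-thorax coupling, and 1D random-field inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swing kinematics, pelvis-thorax coupling, and 1D random-field inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golfswing)
```

`golfswing` analyses driver swings recorded as 3D marker trajectories: eight
markers (pelvis: left/right anterior and posterior superior iliac spines;
thorax: both acromia; club: a grip marker and a marker near the club head),
sampled at 200 Hz in a lab frame whose X axis is the target line and whose Z
axis is vertical. This vignette explains the models and the numerical
choices behind each stage, what the synthetic generator does and does not
emulate, and the package's known limitations.

## Segment angles and discrete parameters

Pelvis and thorax motion is reduced to rotation in the horizontal (x–y)
plane. The pelvis line runs from the right-side centroid (mean of RASIS and
RPSIS) to the left-side centroid; using side centroids instead of the ASIS
pair alone halves independent marker noise without changing the orientation
being measured. The thorax line runs from the right to the left acromion.
Each angle series is the four-quadrant angle of that line to +X, unwrapped,
zeroed at the setup frame, and sign-oriented so that backswing rotation
(away from the target) is positive. The orientation flip is decided by one
rule: the thorax angle at its own extremum must be positive. Degenerate
frames — left and right centroids coinciding — are an error, not a warning,
because every downstream quantity would be meaningless.

Swing events come from the club-head marker alone:

* **start** — first frame with speed ≥ 0.2 m/s, X velocity pointing away
  from the target, and speed sustained above threshold for 0.05 s. The
  debounce rejects address-posture tremor; 0.05 s (10 frames) is long enough
  to bridge noise spikes and far shorter than any real backswing.
* **top** — the speed minimum between the start and the global speed
  maximum. Central differences smear the sample nearest the reversal, and
  when the downswing is much more sharply curved than the backswing the raw
  argmin lands one frame early; the detector therefore intersects the two
  outer slopes of the locally V-shaped speed profile and takes the nearest
  frame to the vertex. On noiseless data this restores exact-frame
  detection.
* **impact** — the acceleration-magnitude peak within ±0.05 s of the global
  speed maximum, after the top. Ball contact is the only event in the swing
  that decelerates the club head at hundreds of m/s², so the peak is
  unambiguous once the search is anchored at the speed maximum.

The five parameters follow directly: `pmax_deg`/`tmax_deg` are absolute
segment rotations between start and top; `xfac_deg` is the thorax-minus-
pelvis angle at the top (positive when the thorax has rotated further);
`sxfac_deg` is the growth of that separation beyond its top-of-backswing
value anywhere in [top, impact], floored at zero; `gcv_mps` is the peak
club-head speed after the top up to impact. The angular-change baseline is
the detected start frame rather than the setup posture; for a smooth start
the two differ by well under the marker-noise floor.

### Filtering

Markers are low-pass filtered before differentiation with a zero-lag
4th-order Butterworth (a 2nd-order filter run forward and backward),
default cutoff 10 Hz — the conventional choice for whole-body sport
movement. Because `signal::filtfilt` starts from zero initial conditions,
series are mirror-extended about their endpoints before filtering and
cropped afterwards; without this the non-zero-mean coordinate series would
ring at both ends. Filtering is switchable (`cutoff_hz = NULL`), and the
noiseless validation runs use it off. One consequence worth knowing: the
10 Hz filter attenuates the club-speed peak by roughly 2–3%, identically
for every player, so group comparisons are unaffected but absolute club
velocities sit slightly below their true peaks.

## Continuous relative phase

Coupling is measured as CRP(t) = φ~pelvis~(t) − φ~thorax~(t), with φ the
phase of the centered Hilbert analytic signal computed over the analysis
interval [start, impact]. Three numerical points matter.

**Padding.** The analytic signal of a finite segment rings at its edges
(the Gibbs phenomenon). Each centered series is mirror-reflected on both
sides before the FFT-based transform and the padding discarded afterwards.
The padding length is a tunable (`pad_fraction`, per side, as a fraction of
the segment length). Its default of 0.20 was calibrated against closed-form
oracles — sinusoid pairs with a known 30° phase offset across a grid of
frequencies and segment lengths — where it gave the smallest worst-case
central error (≈2.8°); longer reflections (50%) leak more time-reversed
energy into the interior and push the worst case above 3°. An
autoregressive-extrapolation padding was prototyped (it is near-exact for
sinusoids) but rejected: low-order forecasts of the strongly nonstationary
swing ramps were unstable across trials.

**Winding anchor.** Unwrapped phases are defined only up to whole turns.
For some boundary phases the padded orbit passes near the origin just
inside an interval edge and picks up a spurious winding, which would offset
the entire CRP curve by ±360°. `crp_series()` fixes the global anchor by
requiring the mid-interval CRP to lie in (−180°, 180°] — the standard
assumption that two segments of one coordinated movement are within half a
coordination cycle of each other mid-stroke. No pointwise wrapping is ever
applied; the adjustment is a single multiple of 360° per curve.

**Sign.** CRP is reported with positive values meaning the pelvis leads in
phase space (`sign_convention = "phase"`). The display convention common in
golf-coupling figures — negative values for a leading pelvis — is available
as an explicit, recorded option (`"display"`) rather than a silent default,
because the two cannot be distinguished from a verbal description alone.

Each trial's CRP is aligned on the frame of maximal pelvis rotation and
time-normalized to 200 nodes. The default `"split"` strategy resamples
[start, m] to 100 nodes and [m, impact] to the remaining 101 (dropping the
duplicate), so node 100 holds the pelvis-rotation maximum of every trial;
an alternative `"shift"` strategy normalizes the whole stroke first and
then shifts the curve onto the alignment node with endpoint replication.
Split is the default because it guarantees the alignment exactly for every
trial regardless of where the maximum falls; both choices are recorded in
the output metadata.

## SPM on coupling curves

Group inference over the 200-node curves uses statistical parametric
mapping. The observation unit is the per-player mean CRP curve, not the
individual trial: SPM's random-field model assumes independent
observations, and trials within a player are anything but. At every node a
pooled-variance two-sample t statistic is computed; residual curves (each
curve minus its group mean) yield a smoothness estimate
FWHM = √(4 ln 2 / v), where v is the mean squared gradient of the
pointwise-standardized residual field. The critical threshold solves the
expected-Euler-characteristic equation for a 1D t field,

$$ P(T_\nu > u) \;+\; \frac{Q-1}{\mathrm{FWHM}}\,
   \frac{\sqrt{4\ln 2}}{2\pi}\,\bigl(1 + u^2/\nu\bigr)^{-(\nu-1)/2} = \alpha^\*, $$

by bisection. Inference is two-sided on |t|, implemented by solving at
α\* = α/2 per tail; this choice (and the curve unit) is stored in the
result's metadata. Clusters are maximal runs of nodes with |t| above the
threshold; cluster-level p-values are deliberately not computed — the
output reports threshold crossings only. Unbalanced groups are supported
natively; `balance_seed` optionally subsamples the larger group to the
smaller size (seeded, reproducible) for users who want the balanced design
of classical SPM software.

The threshold is validated two ways in the test suite: against a seeded
max-statistic permutation oracle (within 5% on smooth Gaussian nulls with
Q = 200, FWHM ≈ 15, n = 6 + 8), and by simulation — the familywise type-I
error over 1,000 null replicates at n = 6 + 6 falls inside 0.05 ± 0.02.

## Group statistics

Discrete parameters are averaged per player, then: Shapiro–Wilk normality
per parameter and sex (reported, never used to switch methods), one-way
ANOVA per parameter with partial eta squared
η~p~² = SS~b~/(SS~b~+SS~w~) — which for the one-way design satisfies
η~p~² = F·df₁/(F·df₁+df₂) exactly, an identity the tests verify to 1e-12 —
and Pearson correlations of each body-movement parameter with club velocity
per sex, with exact two-tailed significance from the t transform of r. The
per-player unit is adopted because published per-player group sizes (6 boys,
8 girls) reproduce the printed correlation significances exactly from the
printed coefficients; no multiple-testing correction is applied across the
five parameters, matching common reporting practice in this literature.
Degrees of freedom are always reported next to every F statistic so that
any mismatch with an external source's observation unit is visible rather
than hidden.

## The synthetic swing generator

`generate_trial()` builds marker trajectories from a kinematic recipe with
analytically known truth, so every downstream stage can be validated
without motion-capture hardware:

* Pelvis and thorax rotate about the vertical axis with raised-cosine
  ramps — C¹ smooth, with closed-form extrema — from 0 to the segment
  amplitude over the backswing and down past zero (to −0.6 of the
  amplitude by default) over the downswing.
* Timing offsets create the coordination structure: `pelvis_onset_lag`
  delays the pelvis at the start of the backswing (boys start thorax-first,
  ~40 ms in the male preset; girls start together), and `transition_lead`
  reverses the pelvis before the thorax near the top, which makes the
  X-factor stretch positive. Because both segment profiles are nearly flat
  at the top, the default 20 ms lead produces stretch values of only a few
  tenths of a degree.
* The club head travels a circular arc whose angular rate is zero at the
  top, rises as a quarter-sine to put the speed peak exactly at impact,
  and then collapses exponentially (τ = 10 ms) — the deceleration spike
  that impact detection keys on. Club-head radius and the setup marker
  geometry are fixed documented constants.
* Isotropic Gaussian noise (default SD 2 mm, typical of active-marker
  optical capture) is added to every coordinate, under a mandatory seed.

Per-player parameters are drawn from sex presets (between-player means and
SDs of pelvis amplitude, thorax amplitude and club speed for elite junior
girls and boys), amplitudes truncated at zero; trial-to-trial jitter is 20%
of the between-player SD, a choice that makes per-player means meaningfully
more precise than single trials without erasing within-player variation.
Swing-phase durations (backswing ≈ 0.9 s, downswing ≈ 0.32 s) and the
transition lead vary mildly between players.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: soft-tissue artifact and marker occlusion
dropouts; three-dimensional trunk motion (lateral bend, forward tilt) that
leaks into transverse-plane angles of real players; club shaft flex, which
decouples the club-head marker from a rigid arc; and any correlation
structure between a player's amplitude, speed and timing parameters, which
are drawn independently here. The generator is a validation instrument for
the pipeline's numerics and inference, not a biomechanical model.

## Power at the study design size

With the preset distributions, the sex gap in pelvis rotation is about one
pooled SD. At the emulated study size (8 + 6 players) a one-way ANOVA
detects such a gap in well under half of simulated cohorts — which is why
the test suite asserts the club-velocity effect (a ~2.6 SD gap, essentially
always detected) at the study size, and verifies detectability of the
pelvis effect on a 60 + 60 cohort, where power exceeds 99.8%. This is a
statement about the design's power, not about the pipeline.

## Degenerate inputs and tie-breaks

Constant signals have undefined phase (error); series shorter than 16
samples are rejected for phase estimation; a pelvis-rotation maximum at the
interval boundary cannot be aligned (error); zero pooled variance at any
SPM node is an error naming the node; groups with fewer than three players
get `NA` correlations and normality statistics inside the pipeline, while
the standalone functions keep strict errors. Trials that fail event
detection are excluded and counted; more than 20% failures aborts the run.
Ties in `which.min`/`which.max` resolve to the earliest frame, fixing event
indices deterministically.

## Known limitations

* Angles are strictly two-dimensional (transverse plane); shoulder or
  pelvis tilt is out of scope by design.
* The CRP endpoints remain the least reliable part of the curve: with
  realistic noise the SPM occasionally flags a short suprathreshold cluster
  in the last few nodes before impact. This is the impact-edge analogue of
  the start-of-stroke Gibbs artifact and should be read as such, not as a
  late-downswing coordination difference.
* The RFT threshold assumes a stationary, Gaussian residual field; the
  permutation threshold is provided as the assumption-free cross-check.
* Default filtering attenuates absolute peak club speed by a few percent
  (group-invariant, see above).

## Problem sizes used by the test suite

The suite simulates cohorts of 8 + 6 players × 10 trials for end-to-end
checks, 60 + 60 × 3 for the power check, 50 noiseless profiles for
parameter recovery, 60 noisy replicates for robustness, 1,000 null
replicates for type-I-error calibration, and 2,000 permutations for the
threshold cross-check; the whole suite runs in well under a minute on one
core. `scripts/acceptance.R` repeats the headline computations at the study
size from a user-supplied seed.
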