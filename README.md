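# golfswing

Sex differences in golf-swing execution are usually described with a handful
of discrete upper-body parameters — how far the thorax and pelvis rotate in
the transverse plane, the X-factor between them at the top of the backswing,
and the club-head velocity at impact. Those numbers ignore *when* the two
segments move relative to each other. `golfswing` implements the full
analysis chain for junior-golfer motion-capture studies that combines both
views: discrete swing parameters from 3D marker trajectories, pelvis–thorax
coordination as a continuous relative phase (CRP) curve, and group inference
over the whole curve with one-dimensional statistical parametric mapping
(SPM). It is aimed at biomechanics researchers who have lab marker data (or
none at all — a synthetic swing generator with analytic ground truth is
included) and want a tested, reproducible pipeline rather than a pile of
one-off scripts.

## What it computes

From eight markers (left/right ASIS and PSIS on the pelvis, both acromia,
two club markers) sampled at 200 Hz:

* **Events** from club-head kinematics: swing start (speed ≥ 0.2 m/s moving
  away from the target, sustained), top of backswing (speed minimum at the
  reversal), impact (acceleration-magnitude peak at the speed maximum).
* **Discrete parameters** per swing: maximal thorax rotation
  T<sub>max</sub> = |θ<sub>thorax</sub>(top) − θ<sub>thorax</sub>(start)|,
  maximal pelvis rotation P<sub>max</sub> (same form), X-factor
  X = θ<sub>thorax</sub>(top) − θ<sub>pelvis</sub>(top), X-factor stretch
  S = max<sub>[top, impact]</sub>(θ<sub>thorax</sub> − θ<sub>pelvis</sub>) − X
  (floored at 0), and club velocity GCV = peak club-head speed before impact.
* **Coupling**: CRP(t) = φ<sub>pelvis</sub>(t) − φ<sub>thorax</sub>(t), with
  φ the unwrapped phase of the centered Hilbert analytic signal; each
  trial's CRP is aligned on maximal pelvis rotation and time-normalized to
  200 nodes.
* **Group statistics**: per-player means, Shapiro–Wilk screen, one-way ANOVA
  with partial eta squared η<sub>p</sub>² = SS<sub>b</sub>/(SS<sub>b</sub>+SS<sub>w</sub>),
  Pearson correlations with exact two-tailed p from
  t = r√(n−2)/√(1−r²).
* **SPM**: a pointwise two-sample t field over the 200 CRP nodes, residual
  smoothness as a FWHM, and the random-field-theory critical threshold t\*
  solving E[EC(u)] = α/2 per tail, where for a 1D t field
  E[EC(u)] = P(T<sub>ν</sub> > u) + (Q−1)/FWHM · √(4 ln 2)/(2π) ·
  (1 + u²/ν)<sup>−(ν−1)/2</sup>. Runs of nodes with |t| > t\* are reported as
  suprathreshold clusters. A seeded max-statistic permutation threshold is
  provided as a nonparametric cross-check.

## Worked example

Simulate a study-sized cohort (8 girls, 6 boys, 10 driver swings each) and
run the whole pipeline:

```r
library(golfswing)
cohort  <- generate_cohort(n_female = 8, n_male = 6, trials_per_player = 10, seed = 42)
results <- run_swing_analysis(cohort, swing_config(balance_seed = 42))
results
#> <swing_analysis> 140 trials (0 excluded), 14 players
#> <swing_spm> two-sample SPM{t}, Q = 200, df = 10
#>   FWHM = 48.94 nodes, |t| threshold = 3.680 (alpha = 0.05)
#>   2 suprathreshold cluster(s): [4, 92], [188, 200]

results$anova[results$anova$parameter %in% c("pmax_deg", "gcv_mps"), ]
#> # A tibble: 2 × 6
#>   parameter      F        p eta_p2   df1   df2
#>   <chr>      <dbl>    <dbl>  <dbl> <dbl> <dbl>
#> 1 pmax_deg   0.585 0.459    0.0465     1    12
#> 2 gcv_mps   22.5   0.000480 0.652      1    12
```

The SPM cluster `[4, 92]` sits before the alignment node (node 100, maximal
pelvis rotation): the sexes differ in pelvis–thorax coupling during the
*backswing*, where the simulated boys start the backswing thorax-first while
the girls rotate both segments together. The club-velocity ANOVA flags the
boys' higher club speed (p < 0.001); the short `[188, 200]` cluster is the
known end-of-interval phase artifact, not a physiological effect. Plots:
`autoplot(results$spm)`, `plot_crp_means(results)`,
`swing_report(results)` renders the tables as markdown.

Trials on disk are analysed the same way:

```r
write_cohort(cohort, "trials/")                 # CSV per trial + metadata.csv
results <- analyze_trials("trials/", out_dir = "out/")   # writes CSV + JSON artifacts
```

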