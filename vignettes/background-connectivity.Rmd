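---
title: "Measuring background connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring background connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgconn)
```

## The model

The package rests on the linear-superposition view of task fMRI: the
observed parcel signal during a task is approximately the sum of a
spontaneous ("intrinsic") component — the same kind of activity recorded
at rest — and a task-evoked response, plus structured nuisance
(physiological signals, head motion) and measurement noise. If that holds,
subtracting an estimate of the evoked component should leave a signal whose
inter-regional correlations resemble resting-state connectivity. Two
estimators of the evoked component are implemented for slow event-related
designs with trials at a fixed 12-s asynchrony:

* **Low-pass filtering (LPF).** Trial-locked activity concentrates at the
  trial frequency (1/12 Hz) and its harmonics. A low-pass filter with a
  16-s cutoff — deliberately below the 12-s task period — removes all of
  it. The cost is that genuinely intrinsic fluctuations above 1/16 Hz are
  removed too: the surviving signal is smoother than rest, its
  correlations are computed from fewer effective degrees of freedom, and
  connectivity estimates are correspondingly more variable and (because
  broadband noise is also removed) systematically stronger.
* **FIR residualization (FIR).** A per-run GLM with one indicator
  regressor per 2-s bin of the 12-s trial window (6 basis functions)
  absorbs the trial-locked mean response of *any* shape — no canonical HRF
  is assumed, and any 6-sample evoked template is inside the model span by
  construction. The residuals retain broadband intrinsic content; the cost
  is the loss of a few degrees of freedom (7 of ~110 columns per run,
  with the intercept) and of whatever intrinsic activity happens to be
  trial-locked.

Both removal paths, and the rest data, then flow through an identical
chain: scrubbing, nuisance-controlled partial correlation, Fisher z,
run averaging. Identical treatment is essential — the comparisons between
methods are only meaningful if the only difference is the removal step.
The nuisance set is partialled out of the FIR residuals as well, even
though it was already in the FIR GLM, to keep the procedures matched.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `highpass_s` | 100 | s | removes scanner drift; standard preprocessing cutoff |
| `lowpass_s` | 16 | s | conservative cutoff below the 12-s trial period |
| `window_trs` | 6 | TR bins | 12-s trial window at TR 2 s |
| `fd_thresh` | 0.5 | mm | framewise-displacement scrubbing threshold |
| `dvars_thresh` | 0.5 | % | DVARS scrubbing threshold |
| `min_retained_frac` | 0.5 | — | below this a run is "insufficient data" and dropped |

The scrubbing order is: quality-control traces are computed from the *raw*
motion parameters and raw parcel series; the resulting mask is applied to
the filtered or residualized series (and to the nuisance matrix) just
before correlation. Judging QC on unfiltered data keeps artifact
localization exact — zero-phase filtering would smear a one-volume glitch
across its neighbors — and matches the common practice of computing FD and
DVARS on minimally processed data. The fraction threshold of 0.5 is a
package default; studies rarely publish their exact exclusion criterion,
so it is exposed as a flag.

DVARS needs a unit decision for parcel-level data: the package defines it
as the root-mean-square (across parcels) of the volume-to-volume signal
change, expressed as a percentage of the grand mean absolute signal level.
This is scale-invariant (doubling the raw signal leaves it unchanged) and
reduces to the familiar percent-signal-change reading when the signal has
a conventional baseline around its mean.

## What the synthetic cohort emulates

`ground_truth_spec()` encodes the study conditions: 56 subjects (cohort
size defaults to the study's; validation suites use 20 for speed, stated
below), one 8-min rest run and four 3.67-min task runs at TR 2 s, trials
every 12 s starting 4 s into the run, 18 per run, 100 parcels in 7
networks (sizes 15, 15, 14, 14, 14, 14, 14).

* **Intrinsic signal.** A stationary AR(1) process (coefficient 0.4) whose
  innovations carry a cross-parcel covariance equal to the subject's true
  correlation matrix. The AR parameter makes the signal red but broadband,
  which is precisely what distinguishes the two removal methods: a
  low-pass filter discards real fast intrinsic fluctuations, FIR does not.
  The square root of the covariance is taken by eigendecomposition rather
  than Cholesky because the nearest-PSD projection can return a singular
  (semidefinite) matrix.
* **True connectivity.** Block structure with r = 0.40 within networks and
  0.05 between, plus symmetric Gaussian jitter (sd 0.05) per subject — the
  ground-truth fingerprint — followed by projection to the nearest
  positive-semidefinite correlation matrix (eigenvalue clipping at zero,
  then rescaling to unit diagonal; simple and deterministic). A note on
  realism: empirical studies report slightly *negative* mean
  between-network z (≈ −0.05), but a uniformly negative between-block
  correlation of that size across seven ~14-parcel blocks is not positive
  semidefinite, so the generator uses a small positive value instead. The
  within-minus-between contrast, which is what the analyses consume, is
  comparable either way.
* **Evoked responses.** A fixed 6-sample template `c(0, .6, 1, .7, .3,
  .1)` placed at every onset, scaled per parcel by `task_amplitude`:
  2.0 (twice the intrinsic sd) in the Visual and Dorsal Attention networks
  and 0.3 elsewhere, reflecting a passive visual-viewing task. Empirical
  amplitudes for this design are not characterized in the literature we
  emulate; these values were fixed once, for testability, and the template
  lies inside the FIR span by construction (any 6-sample shape does).
* **Confounds and noise.** Three physiological signals (AR(1), sd 1)
  loading on every parcel with weights of sd 0.1; white noise of sd 0.5; a
  constant baseline of 1000 arbitrary units so the DVARS percentage has a
  realistic denominator.
* **Motion.** Smooth AR(1) drifts in the six rigid-body parameters plus,
  with probability 0.02 per volume, a spike: a persistent 1-mm translation
  step (the head moves and stays) accompanied by a transient per-parcel
  signal glitch (sd 3 units). A step registers on FD at exactly one
  volume, so at default thresholds the scrubbed volumes are exactly the
  injected ones — which is also what makes the scrubbing stage exactly
  testable. The glitch is kept below the DVARS threshold by default;
  DVARS-driven censoring is exercised by constructed traces in the tests.

What the generator does **not** emulate: hemodynamic convolution and its
regional variability, physiological rhythms (cardiac/respiratory
aliasing), spatial autocorrelation beyond the network blocks, scanner
drift structure beyond what the high-pass removes, and any relationship
between motion and the intrinsic signal. Consequently, passing tests
demonstrate that the *estimators* behave as designed under the
superposition model — they do not certify performance on real BOLD data,
where the removal problem is harder (imperfect linearity, HRF variability,
motion-connectivity coupling).

## Numerical choices

* **Filters.** Fifth-order Butterworth applied forward–backward
  (`signal::filtfilt`): zero phase, maximally flat passband, and the two
  passes square the stopband response, so the 1/12 Hz task frequency is
  attenuated to ~5% amplitude by the 16-s low-pass. Columns are
  reflect-padded by one cutoff period to limit edge transients; the
  high-pass removes column means first. The original study's image-level
  chain used FSL's detrending; a Butterworth high-pass at the same cutoff
  is a self-contained equivalent at these tolerances (a dialect, not a
  reimplementation of their result).
* **Onset mapping.** Onsets are mapped to volumes by rounding
  `onset / tr_s`; in this design all onsets are TR multiples, so the
  mapping is exact. Non-multiple onsets round to the nearest volume.
* **FIR GLM.** Ordinary least squares per run on high-pass-filtered data,
  intercept always included (residuals must be mean-free for correlation).
  Exactly collinear columns (e.g. derivatives of constant confounds in
  degenerate synthetic cases) are dropped with a warning naming them; a
  model still rank-deficient afterwards is an error, not a silent fix.
  Whether the original analysis fit its GLM with FSL's autocorrelation
  correction is unknown; OLS is used here and stated as such.
* **Partial correlation** is realized as residualize-on-nuisance-then-
  Pearson, which equals the textbook partial-correlation formula and
  matches the procedure of controlling a *common* nuisance set — not a
  precision-matrix inversion over all 100 parcels, which would condition
  each pair on the other 98 parcels and answer a different question.
* **Fisher z** clips |r| at 1 − 1e−7 before `atanh`, so identical series
  (r = 1) give a finite, large z instead of infinity; the round trip is
  identity to 1e−6 for |r| ≤ 0.999.
* **Greenhouse–Geisser.** Epsilon per effect from the covariance of
  orthonormal-contrast scores (for the interaction, the Kronecker product
  of the two factors' contrasts); both numerator and denominator df are
  multiplied by epsilon and p-values use the F distribution with the
  fractional df. Effects with a single numerator df need no correction.
  When an effect's sum of squares is exactly zero, F is reported as 0
  (the error term can simultaneously degenerate to zero in that case).
* **Generalized eta-squared** uses the fully-within-design convention:
  the denominator is the effect SS plus *all* error SS including the
  subject SS. Follow-up pairwise tests report uncorrected p-values;
  with three pairwise comparisons, readers preferring a correction can
  apply Holm at a glance.
* **Group summaries of rho** are Fisher-z means reported back-transformed
  ("mean rho(z)"); undefined rho values (constant inputs) are excluded
  pairwise with a logged count.
* **Identification** uses Spearman's rho for consistency with every other
  similarity in the package; the classic fingerprinting literature used
  Pearson. The two differ materially only when the entrywise distribution
  is skewed or has outliers; Pearson on the same vectorized triangles is a
  one-line `stats::cor` call if needed.
* **Seeding.** One master seed; subject *i*'s covariance jitter uses
  stream `seed + i` and its time series `seed + 500000 + i`, so
  regenerating any single subject is independent of cohort size and call
  order.

## Problem sizes in the validation suites

The test suite and `scripts/acceptance.R` exercise the pipeline at 20
subjects under otherwise default conditions (100 parcels, rest + 4 task
runs); small closed-form fixtures use 4–21 parcels. Twenty subjects is
enough for all the direction-of-effect and recovery properties to be
stable across seeds while keeping a full run in tens of seconds. The
ANOVA calibration check uses 500 simulated null datasets of 20 subjects.

## Known limitations

* The generator's evoked response is identical across trials; real
  responses vary, and trial-wise variability is one route by which task
  structure can leak into background connectivity for *both* methods.
* DVARS is defined at the parcel level; voxelwise DVARS on the same data
  would differ in scale, so thresholds are not transferable without the
  flag.
* `run_pipeline()` expects parcel-level time series; extraction from 4-D
  images is out of scope (any parcellation tool can produce the TSV
  inputs).
* With very short runs (under one cutoff period) the filters warn and
  results should not be trusted; the pipeline never silences that warning.
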