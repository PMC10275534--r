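# bgconn

Background functional connectivity from slow event-related fMRI.

## The problem

Resting-state fMRI is the standard way to measure functional connectivity —
the correlated spontaneous activity of distant brain regions — and the
idiosyncratic pattern of a person's connections (their "connectivity
fingerprint") carries stable individual-difference information. Task fMRI
can in principle be mined for the same signal, but task-evoked responses
confound it: two regions that both respond to a stimulus will correlate
even if they are not intrinsically coupled. *Background connectivity* is
the coupling that remains after task-evoked activity has been statistically
removed.

For slow event-related designs (here: trials every 12 s — a 2-s stimulus
followed by 10 s of fixation — 18 trials per 3.67-min run, after a 4-s
initial fixation, TR = 2 s), two removal strategies are available, and this
package implements and compares both:

* **LPF** — a zero-phase low-pass filter with a 16-s cutoff, a conservative
  threshold below the 12-s trial frequency, so all fluctuations at and
  above the task frequency are removed;
* **FIR** — residuals of a per-run GLM with six finite impulse response
  basis functions (one indicator per 2-s TR bin of the 12-s trial window,
  fitting an arbitrary evoked shape without assuming a canonical HRF) plus
  the Power nuisance set (six motion parameters, CSF, white matter and
  global signals, and each of their temporal derivatives; 18 regressors).

Downstream, every dataset (rest, LPF, FIR) is treated identically:
volumes with framewise displacement > 0.5 mm or DVARS > 0.5% are scrubbed;
nuisance-controlled partial correlations between all parcel pairs
(100 parcels, 7 networks) give a 100 × 100 matrix per subject and method;
correlations are Fisher z transformed (z = atanh r) and task runs averaged.
The matrices are then compared via

* **fingerprint similarity** — Spearman's rho between the 4950 unique
  upper-triangle connections of two matrices from the same subject;
* **network structure** — mean within-network vs between-network z, tested
  with a 3 (method) × 2 (connection type) repeated-measures ANOVA with
  Greenhouse–Geisser correction and generalized eta-squared (η²g) effect
  sizes;
* **stability of individual differences** — across-subject Spearman
  correlations of each connection (and of each of the 28 unique cells of
  the 7 × 7 network-collapsed matrix) between methods;
* **subject identification** — matching each subject to their most similar
  matrix in another dataset.

Because a desk-scale package cannot ship a 56-subject fMRI study, the
package includes a first-class synthetic-cohort generator
(`ground_truth_spec()`, `simulate_cohort()`) that reproduces the study
design with a *known* intrinsic covariance per subject (block network
structure plus a subject-specific jitter — the ground-truth fingerprint),
trial-locked evoked responses, confound contamination, white noise and
head-motion spikes. Every claim the package makes is validated against
that ground truth.

## Worked example

```r
library(bgconn)

spec   <- ground_truth_spec(n_subjects = 8, seed = 1)  # study-design defaults
cohort <- simulate_cohort(spec)
cc     <- cohort_connectivity(cohort)        # rest, LPF, FIR matrices/subject
cmp    <- compare_cohort(cc, cohort$atlas)

aggregate(rho ~ comparison, cmp$similarity, median)
#>   comparison       rho
#> 1    lpf_fir 0.7731340
#> 2   rest_fir 0.4316900
#> 3   rest_lpf 0.3636223

cmp$anova[, c("effect", "statistic", "df1", "df2", "p", "ges", "correction")]
#>                   effect   statistic      df1      df2            p        ges         correction
#> 1                 method   20.999073 1.302712 9.118981 8.108804e-04 0.34493700 greenhouse_geisser
#> 2        connection_type 5791.127745 1.000000 7.000000 1.780213e-11 0.99087448               none
#> 3 method:connection_type    2.578766 1.246225 8.723572 1.415063e-01 0.08821227 greenhouse_geisser

round(cmp$identification, 2)
#> rest_lpf rest_fir  lpf_fir
#>     0.88     1.00     1.00
```

Reading the output: each subject's FIR background-connectivity pattern
resembles their own rest pattern more than the LPF pattern does (median
rho 0.43 vs 0.36), while the two removal methods resemble each other most
(0.77); within-network connectivity towers over between-network
connectivity (the `connection_type` main effect); and every subject is
identified from their rest matrix by their FIR matrix (accuracy 1.00).
These are the same qualitative orderings the method is designed to expose,
here at a small demonstration size (8 subjects).

The same analysis runs from a directory tree of TSV files
(`write_cohort()` / `run_pipeline()`), writing per-subject connectivity
matrices, tidy comparison tables, test results and a provenance log.

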