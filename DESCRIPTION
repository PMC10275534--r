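Package: bgconn
Title: Background Connectivity from Slow Event-Related fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring background functional connectivity, the
    region-to-region coupling that remains in task fMRI after task-evoked
    activity has been statistically removed. Implements two removal methods
    for slow event-related designs: low-pass filtering below the task
    repetition frequency, and residualization against a finite impulse
    response (FIR) general linear model. Provides zero-phase temporal
    filtering, nuisance regression, framewise-displacement and DVARS based
    volume scrubbing, parcel-level partial-correlation connectivity with
    Fisher z transformation, connectome fingerprint similarity, within- and
    between-network contrasts, across-subject stability of individual
    differences, subject identification, paired tests and repeated-measures
    ANOVA with Greenhouse-Geisser correction and generalized eta-squared
    effect sizes. Includes a synthetic-cohort generator with known
    ground-truth intrinsic covariance for validation, and an end-to-end
    pipeline over a BIDS-flavored directory tree of parcel time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
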