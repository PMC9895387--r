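Package: restate
Title: Resting-State EEG Microstates and Large-Scale Network Rhythm Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for resting-state EEG analysis built around two estimators:
    polarity-invariant topographic k-means for microstate segmentation
    (global field power peaks, meta-criterion choice of the number of maps,
    two-stage group clustering, backfitting, and the standard temporal
    parameters), and an empirical-Bayes source inversion that places
    large-scale brain-network covariance priors on a spherical-head forward
    model to estimate per-network, per-band rhythm energies. Includes a
    synthetic-EEG cohort generator with planted ground truth, deterministic
    preprocessing (FIR band-pass, notch, average reference, fixed-length
    epoching, amplitude-based artifact rejection), and a repeated-measures
    statistical layer (two-factor within-subject ANOVA, Mauchly's test,
    Greenhouse-Geisser correction, partial eta squared, Bonferroni-corrected
    post hoc paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
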