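Package: fearfuse
Title: Fusion of EEG Activation, Spatial, and Connectivity Features for
    Fear Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-class (fear vs. neutral) EEG decoding pipeline that
    fuses three complementary feature families: differential-entropy band
    power (activation), common-spatial-pattern log-variance (spatial
    distribution), and phase-locking-value connectivity (brain network).
    Trials are classified by a linear support-vector machine on 1-second
    segments with majority voting, and evaluated by leave-one-out
    cross-validation. Includes zero-phase preprocessing (baseline
    correction, 50 Hz notch, broadband and filter-bank Butterworth
    filters), edge-wise one-way ANOVA differential-connectivity
    statistics, a minimal EDF reader/writer, and a seeded synthetic
    two-class EEG session generator with independently controllable
    activation, spatial, and coupling class effects for ground-truth
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
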