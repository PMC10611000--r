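Package: feelpix
Title: Landmark-Based Facial Expression Recognition from Self-Labelled Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating lightweight facial expression
    recognition pipelines that work from 2-D facial landmark coordinates
    rather than raw images. Includes affective stimulus selection from
    valence/arousal norms via k-means clustering, anchor-based landmark
    normalization with an action-unit-motivated 22-point feature subset,
    construction of multi-label emotion datasets with minority-preserving
    undersampling, a per-emotion binary classifier ensemble (support vector
    machines and random forests) tuned by random hyperparameter search under
    stratified five-fold cross-validation, agreement statistics between
    self-reported and detected emotions, and a synthetic-data generator that
    makes the whole pipeline testable without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
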