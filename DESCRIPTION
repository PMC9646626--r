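Package: neckppg
Title: Artifact Classification and Apnea Detection in Neck Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-quality and apnea classification for single-channel neck
    photoplethysmography (PPG) recordings. Provides pulse segmentation, a
    51-feature extractor spanning time-domain pulse morphology, correlogram,
    spectral (short-time Fourier) and upper-envelope descriptors, sliding-window
    segmentation with corruption-threshold labelling, chi-square feature ranking
    with forward sequential selection under leave-one-subject-out
    cross-validation, RBF-kernel support vector machine training with grid
    search, subject-safe data partitions, and a repeated-randomization
    experiment driver. Ships an annotated synthetic neck-PPG cohort generator
    so the full pipeline runs and is testable without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
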