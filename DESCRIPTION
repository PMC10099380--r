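Package: roadhos
Title: Road-Hypnosis Recognition from ECG and EMG via Bispectral Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes road hypnosis (unconscious driving in monotonous
    environments) from driver physiology. Filters ECG and EMG channels,
    estimates the bispectrum by the segment-averaged direct method, extracts
    higher-order-spectral features (sum of log bispectral magnitudes over the
    principal region, its diagonal, and the first-order spectral moment of the
    diagonal), fuses the two channels with principal component analysis to two
    components, and classifies epochs with LDA, QDA, or KNN. Evaluation uses
    accuracy, sensitivity, and specificity under both random shuffle-split and
    subject-grouped k-fold cross-validation, the latter guarding against
    same-subject leakage. A synthetic two-state ECG/EMG cohort generator with
    configurable heart-rate, EMG amplitude, and quadratic-phase-coupling
    contrasts supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
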