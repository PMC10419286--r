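Package: scraman
Title: Single-Cell Raman Chemometrics for Immune-Cell Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing and chemometric analysis of single-cell Raman
    spectra of immune cells: cosmic-spike removal, SNIP baseline
    subtraction, vector normalization, spectral clipping, wavenumber
    calibration against a 4-acetamidophenol reference, spectrum
    aggregation, PCA followed by LDA/random-forest/SVM classification with
    stratified k-fold and leave-one-batch-out cross-validation,
    animal-level majority voting, difference-spectrum band profiling
    against a biochemical band catalogue, and a hierarchical synthetic
    spectrum generator (batch to mouse to cell to spectrum) with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
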