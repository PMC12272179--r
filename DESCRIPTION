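Package: neuroar
Title: Individual Auto-Regressive Modeling of Parcel-Level BOLD Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark pipeline for subject-specific auto-regressive models of
    parcellated fMRI BOLD signals. Provides a synthetic multi-subject cohort
    generator (stable vector auto-regression on a sparse coupling graph with a
    cross-subject shared evoked component), per-run normalization and discrete
    cosine high-pass filtering, functional/spatial/random connectome
    construction with Chebyshev spectral graph operators, a model zoo (uni- and
    multivariate linear AR, multi-layer perceptrons, and Chebnet graph
    convolutional networks) trained by Adam on mean squared error, iterated
    multi-lag prediction, R-squared evaluation with Wilcoxon and
    Benjamini-Hochberg statistics, and prediction-dynamics analyses (power
    spectra and seed-based connectivity from predicted signals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
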