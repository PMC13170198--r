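Package: popsumstats
Title: Population Coding of Motion Summary Statistics in Calcium Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how neural populations encode
    summary statistics (mean direction, variance, category) of random-dot
    motion stimuli from calcium-imaging recordings. Provides a synthetic
    session generator with known ground truth, fluorescence trace
    preprocessing (percentile baseline removal, Savitzky-Golay smoothing,
    IQR-based event detection and quality control), psychometric analysis
    (cumulative-normal fits, d-prime), single-neuron direction tuning with
    permutation-based selectivity, population response curves and their
    slope dynamics, wrapped-normal quantification of categorical bias,
    inverted encoding models and linear support-vector decoding (including
    within- versus between-category discrimination and temporal
    generalization), regression-based representational similarity analysis,
    and cluster-mass permutation inference for time-resolved statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
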