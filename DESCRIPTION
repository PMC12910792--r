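Package: condensatr
Title: Quantification of Nuclear Protein Condensates in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for counting and sizing bright nuclear
    condensates (puncta) in calibrated fluorescence tissue images, together
    with a synthetic-image simulator that provides ground truth for
    validation. Stages cover extended-depth-of-field projection of Z-stacks
    by the local-variance method, rolling-ball background subtraction,
    difference-of-Gaussians enhancement, maxima-seeded watershed
    segmentation with rule-based false-positive rejection, micrometre-
    calibrated area histograms, and per-bin two-group comparisons with
    Holm-Sidak correction. Also includes the Y-maze spontaneous-alternation
    score used alongside such imaging studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
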