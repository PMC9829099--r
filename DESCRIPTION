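Package: pcmrsa
Title: Theory-Guided Pattern Component Modeling for Representational
    Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes condition-by-condition neural similarity structure
    (representational similarity analysis, RSA) into a weighted combination of
    idealized "patterns of interest" (POIs). Builds trial-wise Fisher-z Pearson
    similarity from multivoxel activation patterns, condenses it to a
    condition-level similarity matrix with autocorrelation removal, constructs a
    library of binary (-1/0/+1) model similarity matrices from the experiment
    design, selects the best-fitting POI combination by greedy best-first search
    under the Bayesian information criterion with equivalency branching, and
    validates selections by Monte Carlo cross-validation with reconstructed-
    pattern hold-out regression. Includes synthetic generators for both
    similarity-level and voxel-level data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
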