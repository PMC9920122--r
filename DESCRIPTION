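Package: energyscape
Title: Energy Landscape Analysis of Binarized Multivariate Activity via
    Pairwise Maximum Entropy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits pairwise maximum entropy (Ising) models to binarized
    multivariate time series such as region-of-interest fMRI recordings,
    enumerates the resulting energy landscape over all binary activity
    patterns, extracts local minima, attraction basins and minimax energy
    barriers, builds disconnectivity trees, and screens local-minimum
    states for group differences with Bonferroni-corrected two-sample
    t-tests. Includes an exact Boltzmann sampler for generating synthetic
    two-group datasets with known ground truth, binarization and bilateral
    region-averaging utilities, and an end-to-end pipeline driver for
    network-wise analyses of resting-state data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
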