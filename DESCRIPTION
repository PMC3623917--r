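Package: roughscape
Title: Multi-Scale Roughness and Correlation Analysis of Protein-Water
    Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-scale-resolved analysis of how protein-water interaction
    energy reshapes a protein's potential-energy surface. From uniform-grid
    time series of protein self energy and protein-water interaction energy
    (read from plain columnar files or NAMD-style logs, or simulated from a
    coupled multi-timescale Ornstein-Uhlenbeck mixture with closed-form
    oracles), the package extracts evenly placed windows of n = 2^m points
    spaced tau apart at each time scale tau, computes per-window Pearson
    correlations and population standard deviations of the energy components
    and their sum, classifies each window on the (delta sigma, r) quadrant
    plane, and aggregates per-scale means, distributions and
    smoothing/roughening probabilities into tidy summaries, tables and
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
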