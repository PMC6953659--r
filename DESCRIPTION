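Package: surveygap
Title: Spatial and Taxonomic Bias in Presence-Only Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spatial and taxonomic sampling bias in presence-only
    species occurrence records and prioritizes under-surveyed areas. Builds
    an analysis grid over a study region, classifies cells as sampled or
    un-sampled, maps sampling activity with Thiessen (Voronoi) polygons,
    computes a randomization-calibrated per-ecoregion bias statistic with a
    chi-squared representativeness test, fits a power-law model of sampled
    cells against range size by foraging guild with Tukey contrasts, fits
    Bayesian spatial regressions with an intrinsic conditional autoregressive
    (ICAR) random effect by Markov chain Monte Carlo, and overlays projected
    climate and land-use change to flag priority survey areas. Includes a
    synthetic-landscape generator with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    multcomp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
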