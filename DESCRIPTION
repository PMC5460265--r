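Package: dewpatch
Title: Simulation and Morphometrics of Bubble-Induced Biofilm Disruption
Version: 0.1.0
Authors@R: person("dewpatch", "developers", role = c("aut", "cre"),
    email = "dewpatch@example.org")
Description: Tools to study how a long air bubble disrupts an early-stage
    bacterial biofilm grown on square hydrophobic patches. Provides
    closed-form thin-film hydrodynamics (capillary number, Bretherton
    residual film thickness, evaporation and bubble-passage timescales), a
    synthetic-data generator for heterogeneous extracellular polymeric
    substance (EPS) fields and near-uniform cell monolayers, a mechanistic
    lattice simulator of evaporation-driven film rupture in which receding
    contact lines scrape cells into levees with EPS-dependent pinning, and
    the image statistics used to characterize the resulting hole patterns:
    surface coverage, porosity, hole morphometry, box-counting fractal
    dimension, mean inter-cell distance, hole-growth-curve phase analysis,
    and normalized cross-correlation with a spatial block-permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    FNN,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    digest,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
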