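Package: stsir
Title: Bayesian Spatiotemporal Disease Mapping and Space-Time Cluster Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area spatiotemporal analysis of disease incidence
    from region-by-year count panels: indirect standardization and crude
    standardized incidence ratios (SIR), a retrospective discrete-Poisson
    space-time scan statistic with Monte Carlo inference (cylindrical windows,
    high- and low-rate clusters), six hierarchical Bayesian space-time models
    (BYM spatial effects, second-order random-walk temporal trend, the four
    Knorr-Held space-time interaction types, and a parametric linear-trend
    variant) fitted by MCMC, and a model-comparison battery (DIC, WAIC,
    conditional predictive ordinates, probability integral transform with an
    Anderson-Darling uniformity test, and SIR-scale R-squared). A synthetic
    panel generator with the same generative structure supports end-to-end
    testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
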