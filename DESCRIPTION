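Package: szest
Title: Structurally Enhanced Bayesian Perimetry (ZEST and S-ZEST) Simulation
Version: 0.1.0
Authors@R:
    person("szest", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Bayesian adaptive threshold strategies for macular perimetry on a
    fovea-centered 10-2 grid. Implements the ZEST procedure (discrete prior over
    0-40 dB, Gaussian-cdf likelihood with asymptotes, posterior-mean stimulus
    selection, posterior-SD termination) and its structurally enhanced variant
    S-ZEST, whose priors are individualized from ganglion cell layer (GCL)
    thickness through a point-wise structure-function model. Includes spatial
    likelihood enhancement on a neighbor graph, simulated observers with
    Henson-type variable psychometric slopes and false-response rates, fovea
    localization by normalized cross-correlation, synthetic-eye cohort
    generation with structure-function-consistent thickness maps, a simulation
    harness, and Bland-Altman test-retest statistics with subject-level
    bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
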