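Package: ntdfold
Title: Helix-Coil Ensembles and Enhanced-Sampling Analytics for Linker
    Histone N-Terminal Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the DNA-induced disorder-to-order transition of
    the H1 linker-histone N-terminal domain (NTD) at desk scale. Provides
    sequence-level characterization of NTD subtypes (basic-subregion
    extraction, composition tables, helical-wheel projection and
    amphipathic-face detection), a coarse-grained helix-coil peptide model
    with sequence-dependent propensities, screened sidechain electrostatics
    with a charge-neutralization switch and an optional DNA-rod field, a
    Metropolis Monte Carlo sampler with an exact transfer-matrix oracle,
    collective variables for helicity, compaction and protein-DNA contacts,
    enhanced-sampling engines (well-tempered metadynamics, the well-tempered
    ensemble, temperature replica exchange, parallel-tempered metadynamics
    and umbrella sampling), time-dependent bias-offset reweighting of biased
    trajectories, ensemble analytics (secondary-structure assignment,
    radius-of-gyration baselines, single-linkage clustering, free-energy
    surfaces, convergence checks), and potential-of-mean-force estimation by
    the weighted histogram analysis method with Bayesian-bootstrap errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
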