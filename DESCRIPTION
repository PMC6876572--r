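Package: capdep
Title: Single-Molecule Kinetics of CAP/Cofilin-Driven Actin Filament
    Depolymerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule TIRF observations of
    cyclase-associated protein (CAP/Srv2) hexamers acting at the pointed
    ends of cofilin-decorated actin filaments. Implements the two-state
    end-occupancy kinetic model, labeled-fraction-corrected dwell and
    inter-event-gap estimators for association and dissociation rate
    constants, photobleaching step counting with zero-truncated binomial
    labeling fits, kymograph and trajectory velocimetry with
    Michaelis-Menten saturation fitting, and seeded stochastic generators
    for every input the analysis consumes, so the full estimator chain can
    be validated against known ground truth.
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
    MASS,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
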