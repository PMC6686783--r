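Package: cosflux
Title: Joint CO2-COS Eddy-Covariance Flux Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions net ecosystem CO2 exchange (NEE) into gross primary
    productivity (GPP) and ecosystem respiration using either the classical
    daytime light-response model (FP) or a joint Bayesian inversion that adds
    ecosystem carbonyl sulfide (COS) fluxes as a second, independent
    constraint on canopy photosynthesis (FP+). Includes forward models for
    Lloyd-Taylor respiration, rectangular-hyperbola light response and a
    light-dependent leaf relative uptake ratio; steady-state chamber soil COS
    flux computation with random-forest gap-filling and soil correction of
    ecosystem COS fluxes; a differential-evolution multichain MCMC sampler
    with Gelman-Rubin convergence diagnostics; synthetic half-hourly campaign
    generation with known truth for four site presets; and reporting of
    partitioned GPP series with credible bands, diel composites,
    limit-of-detection flags and campaign-level model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
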