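Package: varconn
Title: Directed Functional Connectivity from Multisite LFP via
    State-Space Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resting-state directed-connectivity analysis for multisite
    local field potential (LFP) recordings: preprocessing (anti-aliased
    down-sampling, zero-phase notch filtering, z-scoring, epoching,
    amplitude-based artifact rejection), multi-trial vector
    autoregressive (VAR) modelling with AIC order selection and adequacy
    diagnostics (multivariate R-squared, Durbin-Watson whiteness, model
    consistency), spectral pairwise-conditional Granger causality
    computed through an innovations state-space form and discrete
    algebraic Riccati equations, band-limited integration over canonical
    frequency bands, and genotype group comparison with scaled Wilcoxon
    rank-sum statistics under false-discovery-rate control.  Includes a
    synthetic-data module (stationary VAR ground truths with line noise
    and movement-artifact contamination; operant biconditional
    discrimination cohorts) so every stage has parameter-recovery
    oracles, plus the biconditional discrimination-ratio behavioural
    statistic.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
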