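Package: bimansem
Title: Bimanual Coordination Scoring, ROI GLM and Path-Analytic Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, simulation-backed pipeline for studying bimanual
    finger coordination and its neural connectivity. Provides scoring of
    button-press correctness for in-phase and anti-phase bimanual tapping,
    pacing-frequency selection from group accuracy tables, a minimal
    first-level general linear model for ROI-averaged BOLD series (canonical
    double-gamma HRF with temporal derivative), and a from-scratch
    maximum-likelihood engine for observed-variable path models (structural
    equation models): fit, standard errors, standardized coefficients, the
    chi-square/GFI/CFI/RMSEA fit battery, AIC/BIC model comparison, greedy
    specification search, and cross-condition comparison of path-significance
    tiers. A synthetic-data module generates press-event streams, multivariate
    ROI observations under known path models, and block-design BOLD-like
    signals, so that every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
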