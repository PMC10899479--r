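Package: dyadconv
Title: Dyadic Convergence Behavior and Its EEG Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-person point-estimation task in
    which dyad members repeatedly estimate the position of a point and may
    spontaneously converge after seeing each other's responses. Provides a
    generative model of dyadic convergence with an exact-agreement mixture, a
    synthetic EEG epoch generator with planted event-related and oscillatory
    effects over 1/f background noise, trial-level behavioral measures
    (discrepancy, adjustment, accuracy) with the associated cleaning rules,
    ERP window means and Morlet wavelet band power with baseline-ratio
    normalization at midline electrodes, hierarchical Bayesian regression
    (hurdle-gamma, Student-t, gamma and cumulative-probit families) with
    participants nested in dyads, and equivalence-style inference via highest
    density intervals with a region of practical equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
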