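Package: enste
Title: Ensemble Transfer Entropy for Non-Stationary Multi-Trial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation of transfer entropy from an ensemble of experimental
    repetitions (trials) of non-stationary time series. Implements the
    Kraskov-Stoegbauer-Grassberger (KSG) nearest-neighbour estimator with
    pooling of delay-embedded state vectors across repetitions, data-driven
    embedding selection by a local-predictor (Ragwitz) criterion,
    trial-shuffling surrogate statistics with permutation testing, and
    reconstruction of information-transfer delays by scanning the assumed
    source-target delay. Includes simulators for the standard validation
    test-beds: delay-coupled Lorenz systems with interval-limited coupling
    and AR(1) pairs with hyperbolic-tangent time-varying coupling. Nearest
    neighbour searches use the maximum norm over batches of independent
    chunks, with an exact brute-force backend and an accelerated k-d tree
    backend behind one contract.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
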