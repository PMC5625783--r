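Package: ed90sim
Title: Simulation of ED90-Targeted Adaptive Phase 2a Dose-Finding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates proof-of-concept phase 2a dose-ranging trials in
    rheumatoid arthritis with a change-from-baseline DAS28 endpoint, and
    evaluates their operating characteristics. Provides Bayesian fits of the
    three-parameter Emax dose-response model (Metropolis-within-Gibbs) and of
    a second-order normal dynamic linear model over the dose index (Gibbs with
    forward-filtering backward-sampling), ED90 estimation from posterior
    draws, interim and final success/futility decision rules, fixed and
    adaptive (ED90-targeted) allocation, and aggregation of simulated trials
    into success/futility rates, type-I error, ED90 selection tables,
    per-dose bias and ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
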