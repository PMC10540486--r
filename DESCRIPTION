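Package: stetrials
Title: Two-Stage Phase II Designs with Nested Survival Endpoints and
    Short-Term-Endpoint Futility Monitoring
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Design, interim monitoring, and simulation tooling for single-arm
    two-stage phase II trials whose primary endpoint is survival (for example
    progression-free survival) dichotomized at a long-term landmark but
    assessed repeatedly on a discrete schedule, so that the repeated
    alive/dead measurements are nested. Provides exact binomial operating
    characteristics and exhaustive design search for Simon-type and
    short-term-endpoint (Kunz-type) two-stage designs; two interim futility
    rules that use every available assessment at the interim look, one based
    on conditional power with discrete-time Kaplan-Meier estimates and one on
    the Bayesian posterior predictive probability of success under negative
    log-Gamma transition priors; a patient-level trial simulator with Weibull
    event times and Poisson accrual; and simulation-based calibration of the
    futility cutoffs to a nominal type I error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
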