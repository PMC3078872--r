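Package: tams
Title: Multi-Stage Trial Designs with Stopping for Lack of Benefit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-arm multi-stage (TAMS) randomized
    trials with time-to-event outcomes that stop early for lack of benefit.
    Intermediate stages compare treatment with control on an intermediate
    outcome (for example progression-free survival) at relaxed one-sided
    significance levels and high power; the final stage uses the definitive
    outcome. The package computes per-stage critical hazard ratios and
    cumulative control-arm event targets by an iterative algorithm, derives
    stage timings under stagewise-uniform accrual and exponential survival,
    evaluates overall and stagewise operating characteristics via
    multivariate normal integrals with square-root event-ratio correlations
    and a cross-outcome attenuation factor, and validates designs by
    Monte-Carlo simulation of whole trials with correlated intermediate and
    definitive event times generated from a Gaussian-copula bivariate
    exponential model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mvtnorm,
    survival,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
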