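Package: sarcscreen
Title: Cost-Effectiveness Analysis of Sarcopenia Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic evaluation of population screening strategies
    for sarcopenia in older adults. Couples a diagnostic-test decision tree
    (true/false positives and negatives at a given prevalence) to a Markov
    cohort model with states healthy, sarcopenia, sarcopenia with
    cardiovascular disease, and death, with falls and fractures modelled as
    within-cycle events. Computes discounted lifetime costs and
    quality-adjusted life years per strategy, incremental cost-effectiveness
    ratios with dominance and extended-dominance handling, net monetary
    benefit, one-way deterministic sensitivity analysis (tornado), and
    probabilistic sensitivity analysis with Beta/Gamma moment-matched
    parameter distributions, cost-effectiveness acceptability curves, and
    strategy-selection probabilities. An individual-level microsimulation of
    the same transition structure serves as an independent stochastic check
    on the deterministic cohort engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
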