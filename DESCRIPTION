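Package: mtcea
Title: Cost-Effectiveness and Value-of-Information Analysis of Meniscal
    Tear Treatment Strategies in Knee Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quarterly-cycle Markov state-transition model comparing three
    management strategies for symptomatic meniscal tear with knee
    osteoarthritis: physical therapy alone, physical therapy followed by
    arthroscopic partial meniscectomy (APM) on persistent pain, and immediate
    APM. Implements cohort-expectation and patient-level microsimulation
    engines with discounted QALY, medical-cost and productivity-cost accrual;
    probabilistic sensitivity analysis with beta/gamma parameter uncertainty;
    ICER frontier construction with dominance and extended dominance; net
    monetary benefit, cost-effectiveness acceptability curves and frontier;
    expected value of perfect and partial perfect information with population
    scaling; and a synthetic trial-record generator with parameter re-estimation
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
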