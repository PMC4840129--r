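Package: nvnscea
Title: Cost-Effectiveness Model of Non-Invasive Vagus Nerve Stimulation for
    Chronic Cluster Headache
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 1-year responder-state cohort model comparing adjunctive
    non-invasive vagus nerve stimulation (nVNS) plus standard of care against
    standard of care alone for chronic cluster headache, from the German
    statutory health insurance perspective. Provides a synthetic patient-level
    trial data generator, parameter estimation (binomial response
    probabilities, gamma-distributed abortive-medication use, an EQ-5D utility
    regression, and an exponential response-loss fit), a deterministic cohort
    engine with four response-trajectory scenarios, probabilistic sensitivity
    analysis with method-of-moments beta/gamma parameterisation, and reporting
    of costs, QALYs, ICER/dominance, cost-effectiveness planes, and
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
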