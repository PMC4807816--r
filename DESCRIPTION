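Package: markovcua
Title: Markov Cohort Cost-Utility Analysis from Weibull Survival Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based cost-utility modelling for oncology treatment
    comparisons. Fits two-parameter Weibull survival functions to
    Kaplan-Meier curve points by linearised least squares, converts them to
    time-dependent per-cycle transition probabilities, runs a three-state
    (progression-free / progressed / dead) Markov cohort trace, and
    accumulates discounted costs and quality-adjusted life years to an
    incremental cost-utility ratio. Includes one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, a synthetic individual-patient-data generator
    for end-to-end validation, and a bundled configuration describing a
    comparison of icotinib and gefitinib as second-line therapy for
    advanced non-small cell lung cancer in China.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
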