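Package: lungscreensim
Title: Microsimulation and Deviance Calibration of Lung Cancer Screening Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Person-level microsimulation of lung cancer natural history
    (Weibull onset, exponential stage dwell times, three cell-type pathways,
    indolent lesions) and periodic radiographic screening (stage-group
    sensitivity, systematic negative error, attendance), assembled into
    two-arm trial simulations in the style of early-detection models such as
    MISCAN. Expected diagnosis count tables are scored against observed
    counts with a Poisson deviance, free parameters are fitted by bounded
    derivative-free search under common random numbers, and nested model
    hypotheses (screening sensitivity, systematic error, over-diagnosis,
    between-arm risk difference) are compared by chi-squared likelihood-ratio
    tests. A synthetic-data generator produces observed-style count tables
    from known ground truth so the whole pipeline is testable without trial
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
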