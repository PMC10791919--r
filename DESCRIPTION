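Package: tactsim
Title: Simulation and Analysis of a Vibrotactile Psychophysics Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a nine-protocol vibrotactile two-alternative
    forced-choice battery (simple/choice response time, static/dynamic
    detection, amplitude discrimination with and without single-site
    adaptation, sequential/simultaneous frequency discrimination and
    temporal order judgement with and without carrier) against synthetic
    observers, extracts thresholds from transformed up-down staircases,
    computes adaptation and inhibition percent-change indices, removes
    outliers by the median-absolute-deviation rule, builds demographically
    comparable groups by greedy propensity-score matching, and compares
    groups with Welch t-tests, factorial linear models with partial
    eta-squared, and Jeffreys-Zellner-Siow Bayes factors.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
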