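Package: ventzone
Title: Oxygenation-Zone Analysis of Breath-by-Breath Ventilator Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scoring the quality of oxygenation during invasive
    mechanical ventilation from breath-by-breath ventilator logs. Each breath
    is classified into an optimal, acceptable or critical oxygenation zone
    from its SpO2 value and its PEEP/FiO2 combination (scored against a
    configurable lower-PEEP/higher-FiO2 table); per-patient endpoints
    (percentage of breaths and of time in each zone, manual and automated
    setting changes, oxygenation alarm episodes) are aggregated per crossover
    phase and compared between ventilation modes with an exact paired
    Wilcoxon signed-rank test. A seeded synthetic ventilator-log generator
    with known ground truth makes every pipeline stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
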