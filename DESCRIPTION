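Package: phcfrontier
Title: Frontier Efficiency and Productivity Analysis for Primary Healthcare Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Static and dynamic efficiency analysis of province-level primary
    healthcare panels. Implements the slacks-based directional distance
    function (SBM-DDF) under variable returns to scale, with and without
    undesirable outputs, over global or contemporaneous frontiers; a two-stage
    decomposition that splits hospital admissions into potentially reasonable
    and unreasonable components and scores the severity of unreasonable
    hospitalization; the Global Malmquist-Luenberger (GML) productivity index
    with its efficiency-change and technology-change decomposition; regional
    aggregation and summary tables; a direct multi-step demand-forecast
    evaluation harness; and a synthetic panel generator with known true
    efficiencies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    randomForest,
    e1071,
    glmnet
Config/testthat/edition: 3
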