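Package: greyhealth
Title: Structural Change and Grey Relational Analysis for Health Workforce Panels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing short compositional time series of health
    workforce attributes (age bands, work experience, educational and
    professional qualifications) and for ranking candidate drivers of a
    resource series. Implements structural change analysis of year-by-category
    percentage panels (structural change values, degrees and contribution
    rates) and Deng-style grey relational analysis (initial-value
    normalization, grey relational coefficients with a discrimination
    coefficient, relational degrees and factor ranking), together with
    validated panel readers/writers, a seeded synthetic-panel generator for
    testing, and an end-to-end report runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
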