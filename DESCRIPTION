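Package: flucea
Title: Cost-Effectiveness Modelling of Enhanced Influenza Vaccines in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness modelling of enhanced seasonal
    influenza vaccination strategies (high-dose versus adjuvanted quadrivalent
    vaccines) in adults aged 65 and over, from a healthcare-payer perspective.
    Implements a one-season cohort decision tree with lifetime discounted
    life-year and QALY losses for premature death, indirect efficacy bridging
    through a common standard-dose comparator, two hospitalization-burden
    definitions (influenza-coded and cardiorespiratory), incremental
    cost-effectiveness analysis (ICER, net monetary benefit, dominance),
    one-way deterministic sensitivity analysis (tornado tables) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, together with a validated parameter-configuration format and a
    synthetic parameter generator with exact algebraic calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
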