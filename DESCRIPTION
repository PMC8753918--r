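Package: traumatriage
Title: Cost-Utility Microsimulation of Prehospital Major Trauma Triage Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level probabilistic cost-utility model of an English
    major trauma system. Simulates synthetic trauma cohorts, routes them
    through a triage decision tree (major trauma centre versus local
    hospital, with secondary transfers), applies a three-stage survival
    cascade (30-day logistic survival equation, 30-day to 1-year
    probabilities, lifetime annual hazards), and accrues discounted
    lifetime quality-adjusted life years and NHS costs. Compares nine
    triage tools with realistic sensitivity/specificity trade-offs via
    full incremental cost-effectiveness analysis (dominance, extended
    dominance, ICERs, net monetary benefit) with deterministic and
    probabilistic sensitivity analyses, plus scenario machinery for
    partial MTC benefit and MTC tariff threshold grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
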