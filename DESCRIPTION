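Package: ectoolkit
Title: Cost-Effectiveness and Budget-Impact Modelling of an Emergency-Care
    Toolkit Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model of a multi-strategy emergency-care
    toolkit intervention in Ugandan regional referral hospitals: a two-arm
    decision tree over five sentinel conditions with disability sub-branches
    for road-traffic-injury survivors, discounted DALY and human-capital
    valuation, one-way deterministic and probabilistic (Monte Carlo)
    sensitivity analysis, national scale-up budget-impact and return-on-
    investment projection, and a synthetic quality-improvement-registry
    cohort generator with case-fatality/odds-ratio recovery for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
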