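Package: pracdelay
Title: Markov Cohort Cost Models of Programs Delaying Permanent Residential Aged Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (Community, permanent residential aged care, Death)
    Markov cohort cost models for community support programs for older people
    with cognitive impairment, compared against standard care. Provides the
    cohort-trace engine with monthly cycles, half-cycle correction and
    discounting, age-dependent life-table mortality with relative-risk
    adjustment, break-even analysis, a deterministic sensitivity-scenario
    engine, national budget-impact scaling, exact 2x2 and t-test subgroup
    statistics, and a synthetic-data module (Gompertz life tables, default
    model specifications, an individual-level microsimulation oracle).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
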