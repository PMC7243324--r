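Package: bargainsim
Title: Simulation and Analysis of Bilateral Pharmaceutical Reimbursement Negotiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study bilateral price negotiations for new
    pharmaceuticals between a regulator (buyer, willingness to pay) and a
    seller (willingness to accept) under a QALY-linked multi-stakeholder
    payoff model. Provides the economic payoff rules of the negotiation game
    (patient benefit, funder pool split, decider bonuses, price-frame
    conversion), ingestion and filtering of participant records (strict
    monotone preferences, offer consistency, attention screening), a seeded
    synthetic-cohort generator emulating the experimental design, a
    Monte-Carlo random-pairing market simulation with convergence
    diagnostics and funder-redistribution accounting, and a battery of
    classical hypothesis tests over margins, frames, roles and agreement
    feasibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
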