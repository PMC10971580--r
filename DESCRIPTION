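Package: pedorcea
Title: Cost-Effectiveness Analysis of Dedicated Pediatric Operating Room Installation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness modelling of installing dedicated
    pediatric operating rooms in a low-resource referral hospital. Implements a
    two-arm decision tree (standard of care versus dedicated pediatric ORs) over a
    one-year horizon, with discounted DALY burden computation (YLL/YLD), an
    annualized multi-payor cost ledger, incremental cost-effectiveness ratios with
    willingness-to-pay classification, one-way (tornado) sensitivity analysis, and
    Monte Carlo probabilistic sensitivity analysis with bootstrap uncertainty
    intervals and cost-effectiveness-plane output. Includes a synthetic
    perioperative patient registry generator so the full pipeline is reproducible
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
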