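Package: hrpsim
Title: High-Risk Pooling Simulation for Health Plan Payment Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates high-risk pooling (HRP) as a supplement to prospective
    risk equalization in regulated health insurance markets. Generates a
    synthetic insured population with a linked, selectively responding health
    survey; rakes the survey to population margins by iterative proportional
    fitting; fits a prospective risk-equalization model on adjuster classes;
    predicts residual spending from survey indicators by stepwise regression
    or random forest; assigns the top share of predicted residual spending to
    a high-risk pool whose compensation threshold is solved so the pool's
    mean residual is zero; finances the pool by a flat-rate contribution from
    the complementary group; and quantifies the trade-off between risk
    selection incentives (subgroup profits and losses, weighted mean absolute
    result) and cost-control incentives (power reduction) across pool sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
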