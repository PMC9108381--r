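Package: ichcea
Title: Cost-Utility Analysis of Minimally Invasive Surgery for Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the real-life implementation of minimally
    invasive surgical (MIS) evacuation of spontaneous intracerebral
    hemorrhage (ICH) from the perspective of a single stroke centre.
    Generates seeded synthetic patient cohorts calibrated to published
    admission and resource-use distributions, screens them against the
    eligibility criteria of the major surgical trials (MISTIE III, DIST,
    ENRICH, INVEST), prices each treatment strategy from tariff line items
    (operating-room minutes, surgical packs, per-diem stays, rehabilitation),
    converts modified Rankin Scale outcomes to quality-adjusted life years
    over a one-year horizon, and computes incremental cost-effectiveness
    ratios, net health benefit, required effect sizes, cost-utility planes
    and cost-effectiveness acceptability curves with bootstrap probabilistic
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
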