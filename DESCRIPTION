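Package: herbrisk
Title: Human Health Risk Assessment of Heavy Metals in Herbal Preparations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exposure and human health risk assessment for potentially toxic
    elements measured in liquid herbal preparations (decoctions/concoctions).
    Implements the standard USEPA-style ingestion risk chain - estimated
    daily intake (EDI), target hazard quotient (THQ), hazard index (HI) and
    lifetime cancer risk (CR) - both as deterministic point estimates and as
    seeded Monte Carlo simulations with percentile (P50/P95) reporting.
    Also provides instrument quality-control statistics (limit of detection
    from calibration blanks, replicate summaries with confidence intervals
    and coefficients of variation, one-sample t-tests against regulatory
    limits), aggregation of GC-MS identified-compound tables into
    compound-class relative-abundance summaries, and a synthetic-data
    generator that emulates replicate elemental measurements with
    non-detects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
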