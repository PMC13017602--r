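Package: crcscreen
Title: Microsimulation of Risk-Based FIT and Colonoscopy Guidance in
    Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level semi-Markov microsimulation of colorectal
    cancer (CRC) natural history (adenoma-carcinoma pathway) used to compare
    screening strategies that guide individuals between biennial fecal
    immunochemical testing (FIT) and 10-yearly colonoscopy. Supports
    age-based, risk-score-based, and quantitative-FIT-based switching
    strategies plus reference strategies, quality-adjusted life-year (QALY)
    accounting with per-event disutilities, colonoscopy demand accounting,
    adherence and stop-age scenarios, and efficiency-frontier analysis of
    strategy outcome tables. Ships an explicitly synthetic "Swiss-like"
    calibration and a published 34-strategy reference outcome table used to
    validate the frontier tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
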