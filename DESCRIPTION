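Package: safetyreview
Title: Config-Driven Interactive Safety-Monitoring Reports for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns SDTM-like long-format clinical trial data (DM, AE, LB, EG,
    VS, EX, CM, MH, DS, SV domains, as CSV or SAS transport v5) into a
    modular, standalone, multi-chapter HTML safety-monitoring report:
    descriptive and adverse-event incidence summary tables with per-cell
    subject links, record-level diffs between consecutive data batches,
    chart data products (visit attendance, adverse-event treemap hierarchy,
    eDish, spaghetti, shift tables), and per-subject patient-profile
    documents on a shared study-day axis. Reports are driven by a YAML
    configuration validated against per-chapter JSON schemas, and a seeded
    synthetic-study generator provides SDTM-like fixtures with known ground
    truth for every computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    haven,
    yaml,
    jsonlite,
    digest,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
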