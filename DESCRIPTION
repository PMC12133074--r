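Package: prenatalITS
Title: Interrupted Time-Series Analysis of GP Care Use by Pregnant Women
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how pregnant women's use of general-practitioner
    (GP) care changed across the COVID-19 pandemic phases, built around routinely
    registered primary-care electronic health records coded with the International
    Classification of Primary Care (ICPC). The package identifies a pregnancy
    cohort from ICPC codes, Dutch free-text note patterns and manual labels,
    applies a reproducible exclusion cascade, normalises daily contact rates per
    1000 registered pregnant patients, fits phase-segmented seasonal least-squares
    regressions with baseline z-comparisons, tests per-code contact frequencies
    with Fisher's exact test, summarises contact-type mix with moving-average and
    locally weighted smoothing, and ships a synthetic EHR generator with a
    ground-truth ledger so the whole pipeline is testable without access to
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
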