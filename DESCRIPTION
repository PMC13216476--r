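Package: srbvkit
Title: Skin Residual Bilirubin Volume Modelling for Transcutaneous
    Bilirubinometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting transcutaneous bilirubin (TcB) readings in
    neonates as a composite of serum bilirubin and a skin residual bilirubin
    volume (SRBV). Provides a two-compartment kinetic simulator of neonatal
    bilirubin under intermittent phototherapy, centre-specific device
    calibration against laboratory serum bilirubin, SRBV estimation and
    band-by-stage summaries, detection of the recovery value flip (RVP) from
    serial paired session readings, and a deterministic SRBV-adjusted
    interpretation rules engine with a rationale trace.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
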