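Package: residuerisk
Title: Pesticide Residue Occurrence, MRL Compliance and Deterministic
    Dietary Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pesticide residue monitoring data in food
    commodities: per-commodity occurrence statistics for censored residue
    measurements, jurisdiction-aware maximum residue limit (MRL) compliance
    checking, deterministic chronic and acute dietary exposure assessment
    (NEDI/%ADI and ESTI/%ARfD hazard quotients across consumer strata), and
    LC-MS multi-residue method validation metrics (matrix effect, recovery,
    RSD, LOD/LOQ, linearity). Ships registry fixtures from a published
    survey of 260 fruit samples from Shanghai and a synthetic sample
    generator with censored log-normal residue levels so every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
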