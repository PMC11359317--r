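Package: faerspv
Title: Pharmacovigilance Signal Detection for FAERS Spontaneous-Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII format. Ingests and deduplicates the
    six-table relational quarterly packets, restricts exposures to
    primary-suspect drugs, maps verbatim preferred terms to a user-supplied
    dictionary with system-organ-class labels and composite term groups,
    computes reporting odds ratios with 95% confidence intervals,
    proportional reporting ratios and chi-squared statistics per drug-event
    pair, and applies the combined ROR/MHRA signal criteria. Downstream
    profiling covers cohort demographics, time-to-onset distributions and
    overlap with cytokine release syndrome. A synthetic FAERS emulator with
    planted drug-event associations makes the whole pipeline testable and
    calibratable without any database download.
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
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
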