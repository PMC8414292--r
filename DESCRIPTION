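Package: carecensus
Title: Daily Care-Demand Metrics for Hospital Inpatient Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts inpatient stay records (admission and discharge dates)
    into per-hospital daily census panels and computes three longitudinal
    care-demand measures: capacity utilization as a percentage of each
    hospital's annual maximum daily occupancy, daily patient turnover
    (admissions, live discharges and deaths relative to the daily census),
    and the daily mean patient clinical complexity level (PCCL) carried by
    the patients present. Summaries are produced by hospital type, day of
    week, weekday versus weekend, week of year and season, together with
    case-level PCCL and length-of-stay tables and annual trend figures.
    A calibrated synthetic-population generator emulates the statistical
    structure of a national one-year general-hospital inpatient dataset
    (hospital taxonomy, occupancy scales, length-of-stay distribution,
    PCCL case mix, weekly and seasonal admission rhythms, year-boundary
    carryover) so the full pipeline runs and is testable without access
    to confidential routine data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    ggplot2,
    yaml,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
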