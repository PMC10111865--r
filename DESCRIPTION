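Package: cnadapt
Title: Time-Resolved Copy-Number Alteration Analysis of Adapting Cell
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of karyotype evolution in cell populations profiled
    by low-coverage whole-genome sequencing. Starting from binned read
    counts, the package corrects GC bias, normalizes counts to
    population-average copy number, detects change points with an exact
    PELT (pruned exact linear time) segmentation, calls gain/loss states
    against a matched parental reference with strict +/-0.5 copy
    thresholds and a minimum-segment-length rule, classifies events as
    whole-chromosome, arm-level, or focal, and computes cohort statistics:
    aneuploidy burden, per-arm gain/loss frequencies over time, CNA-type
    proportions, regression F-test associations between aneuploidies and
    growth, aneuploidy co-occurrence scans, and correlation with external
    cancer arm-frequency tables. A synthetic-data generator produces
    GC-biased, overdispersed binned counts from known (possibly
    subclonal) karyotypes and whole adaptation cohorts with planted
    selection trajectories, so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
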