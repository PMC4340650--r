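Package: diauxr
Title: Growth-Curve Kinetics, Reporter Dynamics and Competition Accounting
    for Diauxic Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microbial batch-culture experiments
    built around the glucose-acetate diauxie of Escherichia coli: log-linear
    growth-rate estimation from plate-reader OD600 time series, two-slope
    diauxic-growth detection and shift-duration estimation, GFP promoter
    reporter activity statistics (transcriptional activity GFP/OD, promoter
    activity dGFP/dt/OD, CRP-activity ratios), substrate uptake and secretion
    rates by regression of extracellular concentration against biomass,
    relative expression and allele-frequency quantification from qPCR cycle
    thresholds, and generation accounting, frequency trajectories and cohort
    statistics for serial-passage competition experiments. A mechanistic
    synthetic batch-culture generator with known ground truth supports
    parameter-recovery and calibration testing of every stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
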