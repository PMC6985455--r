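Package: cinsynergy
Title: Growth-Curve Metrics and Bliss Synergy Analysis for Confluency-Based Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug sensitivity and drug-by-genotype synergy from
    live-cell confluency time series, as used in screens for compounds that
    are selectively toxic to aneuploid or chromosomally unstable (CIN) cells.
    Implements per-well growth summaries (area under the confluency curve by
    the sum-over-timepoints convention or the trapezoid rule, exponential-phase
    cutoff detection by expanding-window log-linear fits, and manual slope
    estimates), per-cell-line control normalization, Bonferroni-corrected
    differential sensitivity testing with volcano-style output, Bliss
    independence synergy scoring with replicate-level significance tests, and
    the accompanying cell-level statistics (contingency tests on mitotic
    phenotype counts, aneuploid-fraction summaries with Wilson intervals,
    rank tests on cell speeds, and per-cell microtubule assembly-rate
    comparisons). A built-in synthetic screen generator with known growth,
    drug, genotype, and interaction parameters makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
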