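Package: synthcohort
Title: Fully Synthetic Patient Cohorts from Published Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates fully synthetic patient-level cohort data from published
    survey summary statistics alone (age-group counts, mean/SD ages, sex counts,
    hazard ratios and exposure prevalences for binary risk factors), with no
    access to any real records. A primary database is built per (age group x
    outcome) subgroup by truncated-normal age sampling, proportional sex
    allocation and hazard-ratio inversion of exposure prevalences; minority
    classes are balanced by duplication. A shuffle-train feedback loop then
    iteratively reshapes within-class joint structure - window-restricted
    Fisher-Yates permutation of age and count-compensated bit flips of the
    binary factors, driven by an Adam-like controller on classifier test
    accuracy - while exactly preserving every marginal count, until a small
    feed-forward network separates the outcome classes. Includes evaluation
    tools: retraining an independent network on the selected snapshot,
    per-class score histograms with an overlap coefficient, and an exact
    marginal-conservation audit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
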