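Package: epitract
Title: Along-Tract White Matter Profiling and Abnormality Taxonomy for
    Epilepsy Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for along-tract (tractometry) group analysis of diffusion
    MRI metrics in drug-resistant focal epilepsy. Builds 100-node tract
    profiles from streamline bundles, summarises them into global and
    five-segment means, recodes hemispheres relative to the ictal onset
    zone, runs ANOVA/ANCOVA comparisons with Fisher LSD contrasts across
    the full tract-by-variable-by-scope grid (patients versus controls and
    seizure-freedom versus seizure-recurrence), and applies a rule-based
    taxonomy of consistent global, consistent segmental, de novo and
    reinforced abnormalities. Includes a seeded synthetic cohort generator
    with planted global or segmental effects for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
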