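Package: rxscorecard
Title: Opioid Prescribing Scorecards with Peer Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quarterly opioid-prescribing scorecards for a multi-division
    health system from prescription-level records: per-prescription morphine
    equivalent daily dose (MEDD) and calculated day supply, a chronic-opioid-use
    registry, five per-provider metrics, per-(division, specialty) IQR-based
    outlier and extreme-outlier thresholds, three tiers of peer-comparison
    reports (provider, leadership, chief medical officer), and the evaluation
    statistics used to track impact (Poisson log-linear quarterly trend,
    pre/post chi-square comparison of guideline-exceedance proportions with
    Wilson confidence intervals). Includes a seeded synthetic-data generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
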