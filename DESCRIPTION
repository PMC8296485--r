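Package: cvdrisk
Title: Cerebrovascular Disease Risk Index Construction and Validation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and validates a community-level cerebrovascular disease
    (CVD) risk index of the Harvard Cancer Risk Index family. Provides
    deterministic diagnostic coding of survey records into binary risk
    factors, log-link Poisson regression for adjusted prevalence odds
    ratios on a binary outcome, conversion of odds ratios into banded risk
    scores, the population-normalised individual risk ratio R with its
    seven-level classification, and cut-point/ROC validation (Youden index,
    DeLong confidence intervals, Cochran-Armitage trend test, Wilcoxon rank
    sum). A seeded synthetic-cohort generator reproduces the statistical
    structure of the source study so the full pipeline is testable without
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
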