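Package: repliscore
Title: Replication Assessment from Reported Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing whether a replication study succeeded,
    starting from nothing more than the summary statistics the original
    and replication reports print. Computes and converts standardized
    effect sizes (Cohen's d_z, d_s, d_av, Hedges g, partial eta squared)
    with standard errors and noncentrality-based confidence intervals,
    conservatively estimates effects from relative p-value bounds,
    compares original and replication effects with a one-tailed
    compatibility Z-test (Fisher-z variant for ANOVA effects), classifies
    each pair into a four-way replication verdict, plans replication
    sample sizes by a publication-bias/uncertainty-corrected cascade with
    safeguard and doubling fallbacks, and aggregates whole replication
    projects. A publication-bias-aware simulator generates study pairs
    with significance-selected originals so every stage of the pipeline
    can be exercised without access to any deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
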