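Package: pvresist
Title: Predicting Hydroxyurea Resistance in Polycythemia Vera from
    Pre-Treatment Blood Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying polycythemia vera patients at risk of
    becoming resistant to first-line hydroxyurea therapy from routinely
    collected pre-treatment data. Provides a synthetic electronic-health-record
    cohort generator with a plantable biomarker interaction, an inclusion
    funnel and window-based resistance labeling adapted from the European
    LeukemiaNet consensus criteria, cross-validated random-forest feature
    ranking, maximally selected log-rank threshold scans for single variables
    and variable pairs with a multiplicative synergy score, quadrant
    enrichment, Kaplan-Meier stratification, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    survival,
    utils,
    withr,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
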