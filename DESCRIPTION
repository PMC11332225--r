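Package: srttlearn
Title: Motor Sequence Learning and Consolidation Analysis for Serial Reaction Time Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of keypress-level serial reaction time task (SRTT)
    data across the lifespan: trial-level outlier exclusion, baseline normalization
    to a pre-learning random run, sequence-specific learning magnitude,
    micro-online/offline gains across practice blocks and rest intervals,
    macro-offline consolidation over 5 h and 24 h delays, mixed ANOVAs with
    Greenhouse-Geisser correction, Tukey pairwise tests, Hedges' g, JZS and
    BIC-approximate Bayes factors, age-trajectory curve selection by AIC, and
    noncentral-F power analysis. Includes a synthetic cohort generator with
    exportable ground truth so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    minpack.lm,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
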