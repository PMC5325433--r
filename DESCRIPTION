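Package: gcpanel
Title: Complementary Membrane-Marker Panels for Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening tumor-enriched membrane markers from
    expression panels with order-statistic thresholds, for semi-quantitative
    immunohistochemistry (IHC) scoring of tissue-microarray cores with
    marker-specific band schemes and subgroup classification, for
    quantifying how marker panels jointly cover cases (including greedy
    panel selection), for two-way average-linkage hierarchical clustering
    with city-block and correlation distances, and for the accompanying
    survival and categorical statistics (Kaplan-Meier, Gehan generalized
    Wilcoxon, Cox proportional hazards, Fisher/chi-square, Mann-Whitney U).
    Includes seeded synthetic-data generators emulating the statistical
    structure of expression, TMA and survival inputs so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
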