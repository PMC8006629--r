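Package: lusmorph
Title: Lung Ultrasound Phenotyping of ARDS Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminates focal from non-focal ARDS lung morphology using the
    12-field semi-quantitative lung ultrasound aeration score. Implements the
    scoring system and its ventral/intermediate/dorsal regional aggregation,
    empirical ROC analysis with Youden cut-point estimation, diagnostic
    accuracy summaries with exact (Clopper-Pearson) confidence intervals,
    Cohen's kappa for inter-observer agreement, Hounsfield-unit aeration
    compartment quantification for CT regions of interest, deterministic
    reconstruction of study cohorts from published ROC operating points, and a
    seeded synthetic-cohort generator calibrated to the published regional
    score distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
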