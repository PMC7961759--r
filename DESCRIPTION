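Package: mprog
Title: Meningioma Progression Subtyping and Progression Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for transcriptome-based meningioma
    progression analysis: resampled consensus clustering for subtype
    discovery with CDF/delta-area model selection and pairwise cluster
    significance testing, empirical-Bayes moderated differential
    expression for one-vs-rest subtype signatures, a single-sample GSEA
    (ssGSEA) implementation and the derived meningioma progression score
    (MPscore), stemness and immune marker scoring, rule-based DNA
    methylation subtype assignment (CIMP, arm-level copy-number loss,
    stemness index rules), and Kaplan-Meier / log-rank / Cox survival
    validation. Ships a synthetic cohort generator that emulates the
    statistical structure of a 179-sample, four-subtype meningioma study
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    randomForest,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    pROC
Config/testthat/edition: 3
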