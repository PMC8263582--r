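Package: sigaudit
Title: Auditing Gene-Expression Signature Classifiers for Overfitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the validation of gene-expression signature
    classifiers for immunotherapy-response prediction. Implements a
    nearest-centroid signature classifier with a continuous score, ROC/AUC
    evaluation with Mann-Whitney tie handling, a size-matched random-gene-set
    resubstitution null that exposes training-AUC inflation when a model is
    trained and evaluated on the same cohort, and a leave-one-cohort-out
    generalization audit. A synthetic multi-cohort expression generator with
    cohort batch shifts and optional injected signal makes every stage of the
    audit testable without access to the original accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
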