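Package: angiopep
Title: Anti-Angiogenic Peptide Classification from Compositional Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible QSAR pipeline for classifying short peptides
    (2-50 residues) as anti-angiogenic or non-anti-angiogenic from their
    primary sequence. Sequences are featurized into compositional molecular
    descriptors (amino-acid, dipeptide and tripeptide composition, plus
    parallel- and series-correlation pseudo-amino-acid composition),
    ranked by a univariate t-test filter, and benchmarked with nested
    resampling (inner holdout tuning, repeated outer 10-fold
    cross-validation) over four learner families: random forest,
    distance-weighted k-nearest neighbours, RBF-kernel support vector
    machines and elastic-net logistic regression. Model performances are
    compared with a Friedman / Iman-Davenport cascade and Finner post-hoc
    adjustment, and elastic-net coefficients are aggregated into a
    feature-importance report. A seeded synthetic-peptide generator with
    class-specific composition biases and planted motifs makes every stage
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    randomForest,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
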