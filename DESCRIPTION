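Package: masegc
Title: Multi-Omics Autoencoder and Stacking Ensemble for Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates exon expression, mRNA expression, miRNA expression and
    DNA methylation profiles for binary tumor-versus-normal classification.
    Modality-specific autoencoders compress each omics layer into a latent
    code, a convex weighted fusion builds a unified patient representation,
    and a stacking ensemble of five base learners (RBF support vector
    machine, random forest, decision tree, adaptive boosting, 1-D
    convolutional network) feeds out-of-fold class probabilities to a
    gradient-boosted-tree meta-classifier. Includes a leakage-aware
    preprocessing pipeline (zero-abundance filtering, k-nearest-neighbour
    imputation, per-feature min-max scaling, moderated-t differential
    screening with Benjamini-Hochberg adjustment), SMOTE-Tomek hybrid
    class balancing, a synthetic multi-omics generator with known ground
    truth, nested cross-validated evaluation and an ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
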