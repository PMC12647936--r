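# masegc — multi-omics autoencoder fusion and stacked classification

`masegc` is an R package for binary tumor-versus-normal classification
from four omics layers measured on the same subjects — exon expression,
mRNA expression, miRNA expression and DNA methylation. It is aimed at
computational-oncology practitioners who have per-modality
feature-by-sample matrices (UCSC-Xena-style TSVs) plus a tumor/normal
label table and want a leakage-aware, reproducible integration-and-
classification pipeline.

## The method

1. **Preprocessing** per modality: features with zero counts in more
   than 60% of samples are removed (expression layers), missing
   methylation values are imputed by k-nearest-neighbour averaging
   (k = 5, missingness-aware distances), features are min–max scaled to
   [0, 1], and an empirical-Bayes moderated two-group t screen keeps
   features with Benjamini–Hochberg adjusted p < 0.001.
2. **Class balancing**: SMOTE oversampling of the minority class
   (synthetics `s = x + u (x_nn − x)`, `u ~ U(0,1)`) to a 1:1 ratio,
   followed by Tomek-link removal of mutual opposite-class nearest
   neighbours until the retained set is link-free.
3. **Latent fusion**: one autoencoder per modality
   (`Z_i^l = σ((W_i^l)ᵀ Z_i^{l−1} + b_i^l)`) trained by Adam on the
   per-sample MSE `L_i = (1/n) Σ_s ‖x_s − x̂_s‖²`; the joint loss is the
   convex combination `Σ λ_i L_i` (`λ_i ≥ 0`, `Σ λ_i = 1`) and the fused
   representation uses the same weights: `Z = Σ λ_i Z_i`.
4. **Stacked classification**: five base learners (RBF SVM, random
   forest, decision tree, AdaBoost, 1-D CNN) emit out-of-fold tumor
   probabilities on the training folds; a gradient-boosted-tree
   meta-classifier (50 rounds) is trained on those five-column meta-rows
   and combines the refitted base learners at prediction time.
5. **Evaluation**: nested stratified cross-validation (everything is
   fitted inside the outer-training fold), reporting accuracy, precision,
   recall, specificity and F1 = 2TP/(2TP+FP+FN) under the tumor-positive
   convention, plus a paired ablation harness (drop one learner, or
   replace the stack by a single boosted-tree classifier).

Every stochastic stage is seeded from one run seed; reruns are
bit-identical.

## Worked example

```r
library(masegc)

# synthetic four-modality dataset with known class structure:
# 40 tumor / 15 normal samples, class effect 3 sd on half the factors
sim <- simulate_multiomics(simulation_config(
  n_samples_per_class = c(40L, 15L), class_effect_size = 3, seed = 7L))
sim$dataset
#> <multiomics_dataset> 55 samples (40 tumor / 15 normal), modalities: exon, mrna, mirna, methylation

cfg <- default_run_config(seed = 3L)
cfg$outer_folds <- 3L; cfg$inner_folds <- 3L; cfg$ae_epochs <- 20L
cfg$learner_params$cnn1d$epochs <- 10L
cfg$alpha <- 0.05  # screen threshold suited to a 55-sample fixture
cv <- cross_validate_pipeline(sim$dataset, cfg, seed = 3L)
cv
#> <cv_result> pooled test metrics:
#> accuracy 0.9818  precision 1.0000  recall 0.9750  F1 0.9873  specificity 1.0000
```

Each of the 55 samples is scored exactly once as a held-out test sample;
the pooled confusion matrix gives 98.2% accuracy, 39 of 40 tumors
recovered (recall 0.975) with no false positives, and all 15 normals
recognized (specificity 1.0). `cv$per_fold` holds the per-fold
validation (inner out-of-fold) and test rows, `cv$aggregate` their means
and standard deviations.

A thin CLI wraps the same functions
(`inst/cli/masegc simulate|preprocess|balance|run|ablate ...`), and
`run_all()` drives the whole pipeline from a YAML config, writing
metrics, per-fold tables and a provenance manifest.

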