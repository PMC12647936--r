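---
title: "Multi-omics autoencoder fusion and stacked classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics autoencoder fusion and stacked classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masegc)
```

## The problem and the model

`masegc` classifies tissue samples as tumor or normal from four omics
layers measured on the same subjects: exon expression, mRNA expression,
miRNA expression (all non-negative, right-skewed, zero-inflated
sequencing-derived values) and DNA methylation (array beta values bounded
in $(0,1)$, with missing entries). The layers are high-dimensional,
heterogeneous in scale, and individually incomplete views of the same
underlying biology, and tumor/normal cohorts are typically very
imbalanced (tumor banks contain far more tumors than adjacent-normal
samples).

The model has two stages.

**Stage 1 — modality-specific autoencoders with convex latent fusion.**
Each modality $i$ is compressed by its own multi-layer autoencoder.
The encoder applies $Z_i^{l} = \sigma\!\left((W_i^l)^\top Z_i^{l-1} + b_i^l\right)$
layer by layer down to a shared latent width; a mirror-structure decoder
reconstructs the input. Reconstruction quality is the per-sample mean
squared error

$$L_i = \frac{1}{n}\sum_{s=1}^{n}\lVert x_{i,s} - \hat x_{i,s}\rVert_2^2,$$

which divides by the sample count only (not the feature count), so wider
modalities contribute proportionally larger losses. The joint training
objective is the convex combination $\sum_i \lambda_i L_i$ with
$\lambda_i \ge 0$, $\sum_i \lambda_i = 1$, and the fused patient
representation uses the *same* weights:

$$Z = \sum_{i} \lambda_i Z_i .$$

Because the fusion is a weighted sum, all modalities must share one
latent dimension.

**Stage 2 — stacked generalization.** Five base learners — an RBF-kernel
SVM, a random forest, a single decision tree, AdaBoost over depth-1
stumps, and a 1-D convolutional network over the latent vector — are
trained on the fused latents. Their positive-class probabilities,
produced strictly out-of-fold on the training set, form a five-column
meta-dataset on which a gradient-boosted-tree meta-classifier (50
rounds, depth 3, learning rate 0.1) is fit. At prediction time the
refitted base learners emit probabilities for the new sample, the
meta-classifier combines them, and labels use threshold 0.5 with ties
going to the tumor class.

## Preprocessing and balancing

The preprocessing order is fixed and enforced by the pipeline runner:

1. **Zero-abundance filter** — features with zero counts in *more than*
   60% of samples are removed (a feature at exactly 60% is retained; the
   comparison is strict). Applied to expression modalities only:
   methylation betas are almost never exactly zero.
2. **KNN imputation** (methylation) — each missing entry is the mean of
   its feature over the $k = 5$ nearest samples; distances are Euclidean
   over co-observed features, normalized by the co-observed count so
   samples with different missingness patterns remain comparable.
   Imputed values necessarily stay within the observed range of their
   feature.
3. **Min–max scaling** to $[0,1]$ per feature. Statistics are fitted on
   training folds only and applied to held-out data with clipping to
   $[0,1]$; constant features map to 0 (a constant carries no
   information, and 0 is stable under clipping).
4. **Moderated-t differential screen** — per feature, a two-group
   t-statistic whose pooled variance is shrunk toward an
   empirical-Bayes prior. The prior degrees of freedom $d_0$ and prior
   variance $s_0^2$ are estimated by method of moments on the
   log sample variances (trigamma inversion); the posterior variance is
   $(d_0 s_0^2 + d s^2)/(d_0 + d)$ and p-values use $d + d_0$ degrees
   of freedom. P-values are Benjamini–Hochberg adjusted and features
   with adjusted $p < 0.001$ are kept. This in-house moderated t
   deliberately replaces a voom-style precision-weight pipeline: it
   keeps the screen self-contained and directly testable, at the cost
   of not modeling a count mean–variance trend — on min–max-scaled
   inputs that trend is weak anyway. Constant features report $p = 1$.

**Class balancing** uses SMOTE followed by Tomek-link removal. SMOTE
synthesizes minority samples $s = x + u\,(x_{nn} - x)$, $u \sim U(0,1)$,
between a minority point and one of its $k = 5$ minority neighbours
until the classes reach a 1:1 ratio; Tomek links (mutual opposite-class
nearest neighbours) are then removed — both members by default, since
the goal is boundary cleaning — and detection/removal repeats until the
retained set contains no link, because removal can itself create new
mutual pairs. Balancing acts on the concatenation of all preprocessed
modality blocks, so the synthetic samples are consistent across
modalities; per-modality balancing would break sample alignment and is
not offered. Balancing happens inside training folds only by default;
`paper_mode = TRUE` reproduces the global pre-split scaling/balancing
order some published pipelines use, which leaks synthetic information
into test folds and is therefore not the default.

## Leakage discipline

Everything fitted — filter feature sets, imputation neighbours, scaling
statistics, screen selections, balancing, autoencoders, base learners,
the meta-classifier — is fitted on the outer-training fold only. Encoders
are frozen before transforming held-out samples. The meta-dataset is
out-of-fold by construction: a sample's meta-row comes from models
trained on inner folds excluding it. The test suite includes a canary: a
deliberately memorizing tree (complexity penalty below zero, minimum
split 2) reaches ~100% in-sample accuracy on random labels, so any
leakage in the meta-feature builder would surface as a near-perfect
out-of-fold column; it stays at chance.

"Validation" metrics are computed from these inner out-of-fold
predictions scored by the fitted meta-classifier; "test" metrics come
from the outer held-out folds, where each sample is scored exactly once
per run. This is one concrete reading of an internal-validation /
held-out-test protocol; others exist, so the two numbers should not be
compared across software.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `zero_thresh` | 0.6 | zero-fraction above which an expression feature is dropped |
| `knn_k` | 5 | imputation neighbours |
| `alpha` | 0.001 | BH-adjusted selection threshold of the screen |
| `smote_k`, `target_ratio` | 5, 1.0 | SMOTE neighbours and target minority/majority ratio |
| `latent_dim` | 8 | shared latent width (fixture scale; 64 is a reasonable cohort-scale value) |
| `fusion_weights` | uniform $1/M$ | $\lambda_i$; the convex constraint is validated |
| `ae_epochs`, `ae_lr`, `ae_batch` | 150, 1e-3, 32 | autoencoder Adam schedule |
| `outer_folds`, `inner_folds` | 10, 5 | outer evaluation folds; inner meta-feature folds |
| `meta_rounds` | 50 | boosting rounds of the meta-classifier |

The SVM grid (cost 0.001/0.01/0.1 × gamma 1/10/100), the random-forest
grid (200/500 trees) and the AdaBoost grid (100/200/300 rounds) are the
published settings and are enumerated exhaustively by `grid_search`
when `do_grid = TRUE`; ties break first-in-grid. The small-cost /
large-gamma SVM grid is unusual but implemented as printed and
overridable. The decision tree runs with pinned defaults (Gini, cp
0.01, no cross-validation pruning) so results do not drift with library
versions. Grid search is off by default at fixture scale: with eight
latent dimensions the fixed settings are already near the ceiling and
the 9-fold larger SVM sweep adds runtime without changing conclusions.

## Architecture and numerical choices

* **Autoencoder**: one hidden layer (input → 4·latent → latent), ReLU
  hidden, **linear bottleneck**, sigmoid output (matching
  min–max-scaled inputs). A linear bottleneck keeps the latent space
  unconstrained; ReLU there zeroes about half the coordinates at
  initialization and measurably hurts downstream separability. Decoder
  weights are untied by default; a `tied` flag shares transposed
  encoder weights for the reading of the decoder that reuses the
  encoder symbol. Training is full-batch-evaluated, mini-batch Adam,
  fully seeded; the loss trace is stored and training aborts with the
  trace attached if the loss goes non-finite.
* **Fusion weights**: uniform $1/M$ by default. The convex constraint
  is part of the published formulation but no selection rule or values
  are given; uniform is the neutral choice and the weights are
  configurable (a validation-fold grid can be layered on top by the
  user).
* **CNN**: the latent vector is a length-$d$ single-channel sequence;
  two valid convolution blocks (kernel 3; 16 then 32 filters), ReLU,
  max-pool 2 where the sequence length allows, inverted dropout 0.3, a
  dense softmax head; Adam, 30 epochs at fixture scale. When the
  sequence is shorter than the kernel the network degrades gracefully
  to the dense head.
* **AdaBoost**: discrete AdaBoost with depth-1 stumps, stopping early
  on a perfect or no-better-than-chance stump; probabilities via the
  logistic map of twice the additive margin.
* **Degenerate screens**: if a fold's screen selects fewer than two
  features for a modality (possible under weak signal at strict
  `alpha`), the pipeline keeps the two smallest-adjusted-p features so
  the autoencoder always has an input; the screen result itself is
  unchanged.
* **Ties**: prediction threshold 0.5 with ties to tumor; nearest-
  neighbour distance ties resolve to the lowest sample index; grid ties
  to the first grid row. Zero-denominator metrics return 0 with an
  explicit degenerate flag.
* **Seeds**: one run seed fans out to per-stage seeds via a stage-name
  hash, so any stage can be reproduced in isolation; identical seeds
  give bit-identical outputs end to end (the boosted-tree meta-learner
  runs single-threaded).

## The synthetic-data generator

Downstream stages are tested without any cohort download by a generator
whose defaults are the study conditions used throughout the tests:
200 tumor / 40 normal samples, six shared latent factors of which half
carry a class mean-shift of 3.0 factor-sd units, Gaussian feature noise
sd 1.0, and fixture-scale feature counts (exon 60, mRNA 50, miRNA 30,
methylation 40). Each modality observes the shared factors (plus two
modality-private, label-free factors) through a block loading matrix:
each signal feature loads on exactly one shared factor with magnitude
drawn from $\pm U(1, 2)$, so every feature the ground truth marks
informative carries a genuine net class shift (dense Gaussian loadings
would allow shifts to cancel across factors, making the ground-truth
labels unfaithful). The other half of each modality's features load
only on private factors and are therefore uninformative, giving the
screen something real to reject.
Expression layers pass through a softplus (non-negative, skewed) with
15% Bernoulli zeroing to exercise the abundance filter; methylation
passes through a logistic squash to $(0,1)$ with 5% masking to exercise
imputation.

What the generator does **not** emulate: RPKM dynamic range, 450K beta
bimodality, probe-level artefacts, batch structure, or biological
correlation networks. Passing the recovery tests therefore shows the
pipeline's machinery is sound and leak-free at strong signal-to-noise;
it does not certify performance on real cohorts.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at
fixture scale: 240 samples, ~60 features per modality before screening,
latent width 8, 10 outer × 5 inner folds, 150 autoencoder epochs, fixed
base-learner settings (random forest 200 trees, AdaBoost 80 rounds, CNN
30 epochs). These sizes are the package's fixture-scale defaults chosen
so a complete nested run finishes in about two minutes on one CPU;
cohort-scale analyses should raise `latent_dim`, the epoch counts and
`inner_folds` (10 is the published choice) and enable `do_grid`.

## Known limitations

* The per-modality resampled class counts some published tables report
  (different tumor/normal totals per modality after balancing) cannot
  be produced by this pipeline: balancing per modality would destroy
  the sample alignment that fusion requires. `masegc` balances the
  aligned, integrated dataset only.
* The moderated-t screen assumes approximately Gaussian scaled
  intensities within class; for raw counts it is a deliberate
  simplification (no precision weights).
* The 1-D CNN treats latent coordinates as an ordered sequence; the
  order is an artefact of training, so its convolutional prior is weak.
  It still adds ensemble diversity, which is its role here.
* No probability calibration, multiclass support, AUC reporting, or
  batch correction; external-cohort harmonization is out of scope.
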