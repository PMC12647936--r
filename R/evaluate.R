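# Confusion-matrix metrics, the nested cross-validated pipeline, and the
# ablation harness. Tumor is the positive class throughout: recall measures
# tumor detection, specificity measures normal-tissue recognition.

#' Confusion counts under the tumor-positive convention
#'
#' @param y_true,y_pred binary vectors (1 = tumor) of equal length.
#' @return a `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_masegc("input", "length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' The five classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), recall TP/(TP+FN),
#' specificity TN/(TN+FP) and F1 = 2TP/(2TP+FP+FN) (identically the
#' harmonic mean of precision and recall). Zero-denominator cases return
#' 0 and are flagged as degenerate rather than erroring, so ablation
#' sweeps never abort.
#'
#' @param counts a [confusion_counts] object.
#' @return a `metrics_report`: the five metrics, the counts, and a
#'   `degenerate` character vector naming any zero-denominator metric.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop_masegc("input", "no samples to score")
  degenerate <- character(0)
  if (counts$TP + counts$FP == 0) degenerate <- c(degenerate, "precision")
  if (counts$TP + counts$FN == 0) degenerate <- c(degenerate, "recall")
  if (counts$TN + counts$FP == 0) degenerate <- c(degenerate, "specificity")
  if (2 * counts$TP + counts$FP + counts$FN == 0) degenerate <- c(degenerate, "f1")
  structure(list(accuracy = (counts$TP + counts$TN) / total,
                 precision = safe_ratio(counts$TP, counts$TP + counts$FP),
                 recall = safe_ratio(counts$TP, counts$TP + counts$FN),
                 specificity = safe_ratio(counts$TN, counts$TN + counts$FP),
                 f1 = safe_ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN),
                 counts = counts, degenerate = degenerate, rounding = 4L),
            class = "metrics_report")
}

#' F1 as the harmonic mean of precision and recall
#'
#' Used for worked-example arithmetic on printed (precision, recall)
#' pairs: `2 P R / (P + R)`.
#'
#' @param precision,recall reals in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  specificity %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$specificity))
  if (length(x$degenerate)) cat("degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

metrics_vector <- function(r) {
  c(accuracy = r$accuracy, precision = r$precision, recall = r$recall,
    f1 = r$f1, specificity = r$specificity)
}

# Preprocess every modality for one outer fold: filter/impute on each
# split, scaling and screening statistics fitted on the training split
# only (global_stats = TRUE reproduces pre-split fitting, paper mode).
preprocess_fold <- function(dataset, train_ids, test_ids, config) {
  out_train <- list(); out_test <- list()
  for (mod in names(dataset$modalities)) {
    m <- dataset$modalities[[mod]]
    tr <- omics_matrix(m$values[, train_ids, drop = FALSE], m$modality)
    if (m$modality %in% EXPRESSION_MODALITIES) {
      tr <- filter_low_abundance(tr, config$zero_thresh)
    }
    tr <- knn_impute(tr, config$knn_k)
    st <- fit_minmax(tr)
    tr <- apply_minmax(tr, st)
    scr <- moderated_differential_screen(tr, dataset$labels, config$alpha)
    keep <- scr$feature[scr$selected]
    if (length(keep) < 2L) keep <- scr$feature[order(scr$adj_p)][seq_len(min(2L, nrow(scr)))]
    tr <- omics_matrix(tr$values[keep, , drop = FALSE], tr$modality)
    out_train[[mod]] <- tr
    if (length(test_ids)) {
      te <- omics_matrix(m$values[st$feature_ids, test_ids, drop = FALSE], m$modality)
      te <- knn_impute(te, min(config$knn_k, max(1L, length(test_ids) - 1L)))
      te <- apply_minmax(te, st)
      out_test[[mod]] <- omics_matrix(te$values[keep, , drop = FALSE], te$modality)
    }
  }
  list(train = out_train, test = out_test)
}

# Balance the aligned training samples once on the concatenated feature
# space, then split the balanced rows back into per-modality blocks so
# every modality sees the same (original + synthetic) samples.
balance_fold <- function(mats_train, y_train, config, seed) {
  widths <- vapply(mats_train, function(m) nrow(m$values), integer(1))
  Xc <- do.call(cbind, lapply(mats_train, function(m) t(m$values)))
  rs <- smote_tomek(Xc, y_train, k = min(config$smote_k, min(table(y_train)) - 1L),
                    target_ratio = config$target_ratio, seed = seed,
                    removal_policy = config$removal_policy)
  offsets <- c(0L, cumsum(widths))
  mats_bal <- list()
  ids <- sprintf("b%04d", seq_len(nrow(rs$X)))
  for (i in seq_along(mats_train)) {
    block <- t(rs$X[, (offsets[i] + 1L):offsets[i + 1L], drop = FALSE])
    dimnames(block) <- list(rownames(mats_train[[i]]$values), ids)
    mats_bal[[names(mats_train)[i]]] <- omics_matrix(block, mats_train[[i]]$modality)
  }
  list(mats = mats_bal, y = rs$y, provenance = rs$provenance)
}

active_specs <- function(config, seed) {
  specs <- default_learner_specs(seed)
  for (nm in names(config$learner_params %||% list())) {
    specs[[nm]]$params <- utils::modifyList(specs[[nm]]$params, config$learner_params[[nm]])
  }
  excl <- config$exclude %||% "none"
  map <- c(svm = "svm_rbf", rf = "random_forest", dt = "decision_tree",
           adaboost = "adaboost", cnn = "cnn1d")
  if (excl %in% names(map)) specs[[map[[excl]]]] <- NULL
  specs
}

fit_fold_model <- function(Z_train, y_train, config, seed) {
  excl <- config$exclude %||% "none"
  if (identical(excl, "meta")) {
    # single boosted-tree classifier on the fused latents (no stacking)
    folds <- make_fold_plan(y_train, config$inner_folds, derive_seed(seed, "inner_folds"))
    oof <- rep(NA_real_, length(y_train))
    for (k in sort(unique(folds))) {
      fit <- fit_meta_xgb(Z_train[folds != k, , drop = FALSE], y_train[folds != k],
                          nrounds = config$meta_rounds, seed = derive_seed(seed, "meta"))
      oof[folds == k] <- stats::predict(fit, xgboost::xgb.DMatrix(unname(Z_train[folds == k, , drop = FALSE])))
    }
    fit <- fit_meta_xgb(Z_train, y_train, nrounds = config$meta_rounds,
                        seed = derive_seed(seed, "meta"))
    list(kind = "no_meta", fit = fit, oof_prob = oof,
         predict = function(Znew) {
           pr <- stats::predict(fit, xgboost::xgb.DMatrix(unname(Znew)))
           list(labels = as.integer(pr >= 0.5), prob = as.numeric(pr))
         })
  } else {
    model <- train_stacking(Z_train, y_train, specs = active_specs(config, seed),
                            inner_folds = config$inner_folds, seed = seed,
                            do_grid = isTRUE(config$do_grid),
                            meta_rounds = config$meta_rounds)
    vp <- validation_predictions(model)
    list(kind = "stacking", fit = model, oof_prob = vp$prob,
         predict = function(Znew) predict(model, Znew))
  }
}

#' Nested cross-validated evaluation of the full pipeline
#'
#' Splits the aligned dataset into `outer_folds` stratified folds; within
#' each outer training set runs preprocess -> balance -> autoencode ->
#' stack with every statistic fitted on that training set only, then
#' scores the untouched outer test fold. Validation metrics come from the
#' inner out-of-fold predictions, test metrics from the outer held-out
#' fold; each sample is scored exactly once as a test sample.
#'
#' @param dataset a `multiomics_dataset` from [align_samples] or
#'   [simulate_multiomics].
#' @param config a pipeline configuration, see [default_run_config].
#' @param seed integer run seed (fans out to per-stage seeds).
#' @return a `cv_result`: per-fold metric table, aggregate mean/sd,
#'   pooled test-confusion metrics, and provenance.
#' @export
cross_validate_pipeline <- function(dataset, config = default_run_config(), seed = 1L) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  y <- unname(dataset$labels$labels[dataset$sample_ids])
  folds <- make_fold_plan(y, config$outer_folds, derive_seed(seed, "outer_folds"))
  per_fold <- list()
  pooled_true <- integer(0); pooled_pred <- integer(0)
  failed <- 0L
  weights <- config$fusion_weights %||% rep(1 / length(dataset$modalities),
                                            length(dataset$modalities))
  for (f in sort(unique(folds))) {
    res <- tryCatch({
      train_ids <- dataset$sample_ids[folds != f]
      test_ids <- dataset$sample_ids[folds == f]
      y_train <- y[folds != f]; y_test <- y[folds == f]
      pp <- preprocess_fold(dataset, train_ids, test_ids, config)
      if (isTRUE(config$balance)) {
        bal <- balance_fold(pp$train, y_train, config, derive_seed(seed, paste0("balance_f", f)))
        mats_train <- bal$mats; y_fit <- bal$y
      } else {
        mats_train <- pp$train; y_fit <- y_train
      }
      ae_cfg <- train_config(epochs = config$ae_epochs, lr = config$ae_lr,
                             batch_size = config$ae_batch, latent_dim = config$latent_dim,
                             seed = derive_seed(seed, paste0("ae_f", f)))
      trained <- train_multiomics_autoencoders(mats_train, ae_cfg, weights)
      Z_train <- trained$bundle$Z
      Z_test <- encode_multiomics(trained$models, pp$test, weights)$Z
      model <- fit_fold_model(Z_train, y_fit, config, derive_seed(seed, paste0("stack_f", f)))
      val_metrics <- classification_metrics(
        confusion_counts(y_fit, as.integer(model$oof_prob >= 0.5)))
      pred <- model$predict(Z_test)
      test_metrics <- classification_metrics(confusion_counts(y_test, pred$labels))
      list(fold = f, val = val_metrics, test = test_metrics,
           y_test = y_test, pred = pred$labels)
    }, masegc_error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning(sprintf("fold %d failed: %s", f, conditionMessage(res)))
      if (failed > 3L) stop_masegc("run", "more than 3 folds failed; aborting")
      next
    }
    pooled_true <- c(pooled_true, res$y_test)
    pooled_pred <- c(pooled_pred, res$pred)
    per_fold[[length(per_fold) + 1L]] <- res
  }
  fold_table <- do.call(rbind, lapply(per_fold, function(r) {
    data.frame(fold = r$fold, split = c("validation", "test"),
               rbind(metrics_vector(r$val), metrics_vector(r$test)))
  }))
  agg <- lapply(c(validation = "validation", test = "test"), function(s) {
    sub <- fold_table[fold_table$split == s, c("accuracy", "precision", "recall", "f1", "specificity")]
    list(mean = colMeans(sub), sd = apply(sub, 2L, stats::sd))
  })
  structure(list(per_fold = fold_table,
                 aggregate = agg,
                 pooled_test = classification_metrics(confusion_counts(pooled_true, pooled_pred)),
                 fold_ids = folds, failed_folds = failed,
                 seed = seed, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> pooled test metrics:\n")
  print(x$pooled_test)
  invisible(x)
}

#' Ablation sweep over ensemble components
#'
#' Runs one full cross-validated evaluation per exclusion with identical
#' seeds, so every run shares the same outer fold assignment (paired
#' design). `"meta"` replaces the stack by a single boosted-tree
#' classifier on the fused latents.
#'
#' @param dataset a `multiomics_dataset`.
#' @param config pipeline configuration.
#' @param excludes character vector from `none, svm, rf, dt, adaboost,
#'   cnn, meta`.
#' @param seed integer seed shared by all runs.
#' @return list with `table` (one metrics row per setting, test split,
#'   pooled) and `runs` (the full `cv_result` objects).
#' @export
ablation_run <- function(dataset, config = default_run_config(),
                         excludes = c("none", "svm", "rf", "dt", "adaboost", "cnn", "meta"),
                         seed = 1L) {
  excludes <- match.arg(excludes, c("none", "svm", "rf", "dt", "adaboost", "cnn", "meta"),
                        several.ok = TRUE)
  runs <- list()
  rows <- list()
  for (ex in excludes) {
    cfg <- config
    cfg$exclude <- ex
    cv <- cross_validate_pipeline(dataset, cfg, seed)
    runs[[ex]] <- cv
    rows[[ex]] <- data.frame(setting = ex, t(metrics_vector(cv$pooled_test)))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))), runs = runs)
}
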