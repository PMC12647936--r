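# Stacked generalization: out-of-fold meta-features from five base
# learners, a gradient-boosted-tree meta-classifier (50 rounds), and the
# nested fold bookkeeping that keeps the meta level leakage-free.

#' Stratified k-fold assignment
#'
#' Produces a fold id per sample such that folds partition the samples
#' exactly and class ratios are preserved within one sample of parity.
#'
#' @param y binary labels.
#' @param n_folds fold count.
#' @param seed integer seed.
#' @param stratified stratify by class (default) or plain shuffle.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
make_fold_plan <- function(y, n_folds = 10L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  if (n_folds < 2L || n_folds > n) stop_masegc("plan", "need 2 <= n_folds <= n")
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    }
    folds
  })
}

f1_from_pred <- function(y_true, y_pred) {
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Exhaustive grid search for a base learner
#'
#' Evaluates every row of the spec's hyperparameter grid by stratified
#' cross-validation on the supplied (training-fold) data, scoring by F1;
#' ties are broken by first-in-grid order. A `NULL` grid returns the
#' spec's fixed parameters untouched.
#'
#' @param spec a [base_learner_spec].
#' @param X numeric matrix, samples x features.
#' @param y binary labels.
#' @param n_folds folds for the inner evaluation, default 3.
#' @param seed integer seed for the fold plan.
#' @return list with `params` (best setting), `scores` (per grid row),
#'   `n_candidates`.
#' @export
grid_search <- function(spec, X, y, n_folds = 3L, seed = 1L) {
  stopifnot(inherits(spec, "base_learner_spec"))
  if (is.null(spec$grid) || nrow(spec$grid) == 0L) {
    return(list(params = spec$params, scores = numeric(0), n_candidates = 0L))
  }
  folds <- make_fold_plan(y, n_folds, seed)
  for (k in seq_len(n_folds)) {
    if (length(unique(y[folds != k])) < 2L) {
      stop_masegc("stratification", "a training fold contains a single class")
    }
  }
  scores <- numeric(nrow(spec$grid))
  for (g in seq_len(nrow(spec$grid))) {
    params <- as.list(spec$grid[g, , drop = FALSE])
    f1s <- numeric(n_folds)
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      fit <- fit_learner(spec, X[tr, , drop = FALSE], y[tr], params = params)
      p1 <- predict_proba(fit, X[!tr, , drop = FALSE])[, "1"]
      f1s[k] <- f1_from_pred(y[!tr], as.integer(p1 >= 0.5))
    }
    scores[g] <- mean(f1s)
  }
  best <- which.max(scores)  # first maximum wins ties
  list(params = as.list(spec$grid[best, , drop = FALSE]),
       scores = scores, n_candidates = nrow(spec$grid))
}

#' Out-of-fold meta-features from the base learners
#'
#' For each inner fold, every active learner is trained on the remaining
#' folds and emits the positive-class probability for the held-out fold;
#' concatenation over folds yields one meta-row per sample produced by
#' models that never saw that sample.
#'
#' @param specs named list of [base_learner_spec].
#' @param folds integer fold ids from [make_fold_plan] covering all rows.
#' @param X numeric matrix, samples x features.
#' @param y binary labels.
#' @return matrix n x length(specs) of probabilities, attribute
#'   `"fold_ids"` recording which fold produced each row.
#' @export
build_meta_features <- function(specs, folds, X, y) {
  if (any(is.na(folds)) || length(folds) != nrow(X)) {
    stop_masegc("plan", "fold plan must cover every sample")
  }
  meta <- matrix(NA_real_, nrow(X), length(specs),
                 dimnames = list(NULL, names(specs)))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    for (nm in names(specs)) {
      fit <- fit_learner(specs[[nm]], X[tr, , drop = FALSE], y[tr])
      meta[!tr, nm] <- predict_proba(fit, X[!tr, , drop = FALSE])[, "1"]
    }
  }
  if (anyNA(meta)) stop_masegc("plan", "coverage gap: some sample appears in no fold")
  attr(meta, "fold_ids") <- folds
  meta
}

fit_meta_xgb <- function(meta, y, nrounds = 50L, max_depth = 3L, eta = 0.1, seed = 1L) {
  dtrain <- xgboost::xgb.DMatrix(unname(meta), label = y)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1L, seed = as.integer(seed)),
                     data = dtrain, nrounds = nrounds, verbose = 0L)
}

#' Train the stacking ensemble
#'
#' Builds out-of-fold meta-features on the (outer-)training data, fits the
#' boosted-tree meta-classifier (50 rounds, depth 3, learning rate 0.1) on
#' them, and refits every base learner on the full training data for
#' deployment.
#'
#' @param Z numeric matrix (fused latent), samples x features.
#' @param y binary labels.
#' @param specs named list of [base_learner_spec]; defaults to the five
#'   learners of [default_learner_specs]. Deactivate learners by passing a
#'   subset (ablations).
#' @param inner_folds inner fold count for the meta-features, default 10.
#' @param seed integer seed.
#' @param do_grid run [grid_search] per learner on the training data
#'   before stacking (off by default at fixture scale).
#' @param meta_rounds boosting rounds of the meta-classifier.
#' @return a `stacking_model`.
#' @export
train_stacking <- function(Z, y, specs = NULL, inner_folds = 10L, seed = 1L,
                           do_grid = FALSE, meta_rounds = 50L) {
  stopifnot(is.matrix(Z), nrow(Z) == length(y))
  y <- as.integer(y)
  specs <- specs %||% default_learner_specs(seed)
  if (do_grid) {
    for (nm in names(specs)) {
      gs <- grid_search(specs[[nm]], Z, y, seed = derive_seed(seed, paste0("grid_", nm)))
      specs[[nm]]$params <- utils::modifyList(specs[[nm]]$params, gs$params)
    }
  }
  folds <- make_fold_plan(y, inner_folds, derive_seed(seed, "inner_folds"))
  meta <- build_meta_features(specs, folds, Z, y)
  meta_fit <- fit_meta_xgb(meta, y, nrounds = meta_rounds,
                           seed = derive_seed(seed, "meta"))
  base_fits <- lapply(specs, function(sp) fit_learner(sp, Z, y))
  structure(list(specs = specs, base_fits = base_fits, meta_fit = meta_fit,
                 meta_features = meta, fold_ids = folds, y = y,
                 meta_rounds = meta_rounds, seed = seed,
                 active = names(specs)),
            class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model> base learners: %s; meta: xgboost (%d rounds)\n",
              paste(x$active, collapse = ", "), x$meta_rounds))
  invisible(x)
}

#' Predict with a stacking model
#'
#' Base-learner probabilities form the meta-row, the meta-classifier emits
#' the final tumor probability, and the label uses threshold 0.5 with ties
#' going to the positive (tumor) class.
#'
#' @param object a `stacking_model`.
#' @param Z numeric matrix with the training latent width.
#' @param ... unused.
#' @return list with `labels` (0/1) and `prob` (tumor probability).
#' @export
predict.stacking_model <- function(object, Z, ...) {
  stopifnot(is.matrix(Z))
  meta <- vapply(object$base_fits, function(f) predict_proba(f, Z)[, "1"],
                 numeric(nrow(Z)))
  if (nrow(Z) == 1L) meta <- matrix(meta, nrow = 1L)
  prob <- stats::predict(object$meta_fit, xgboost::xgb.DMatrix(unname(meta)))
  list(labels = as.integer(prob >= 0.5), prob = as.numeric(prob))
}

#' Out-of-fold validation predictions of a stacking model
#'
#' Applies the fitted meta-classifier to the stored out-of-fold meta
#' features; each row was produced by base models that never saw that
#' sample.
#'
#' @param model a `stacking_model`.
#' @return list with `labels` and `prob` for the training samples.
#' @export
validation_predictions <- function(model) {
  prob <- stats::predict(model$meta_fit, xgboost::xgb.DMatrix(unname(model$meta_features)))
  list(labels = as.integer(prob >= 0.5), prob = as.numeric(prob))
}
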