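# Base learners behind a common fit / predict-probability contract.
#
# SVM (RBF), random forest and decision tree are provided by e1071,
# randomForest and rpart. AdaBoost (discrete SAMME with depth-1 rpart
# stumps) and the 1-D CNN are implemented here; both honour the same
# contract and are seeded for reproducibility.

LEARNER_KINDS <- c("svm_rbf", "random_forest", "decision_tree", "adaboost", "cnn1d")

default_grid <- function(kind) {
  switch(kind,
         svm_rbf = expand.grid(cost = c(0.001, 0.01, 0.1), gamma = c(1, 10, 100)),
         random_forest = expand.grid(ntree = c(200L, 500L)),
         adaboost = expand.grid(n_estimators = c(100L, 200L, 300L)),
         decision_tree = ,
         cnn1d = NULL)
}

#' Specify a base learner
#'
#' @param kind one of `"svm_rbf"`, `"random_forest"`, `"decision_tree"`,
#'   `"adaboost"`, `"cnn1d"`.
#' @param params named list of fixed hyperparameters (overrides defaults).
#' @param grid data.frame hyperparameter grid for [grid_search]; `NULL`
#'   uses the built-in grid for the kind (SVM: cost 0.001/0.01/0.1 x
#'   gamma 1/10/100; RF: 200/500 trees; AdaBoost: 100/200/300 rounds;
#'   decision tree and CNN have no grid).
#' @param seed integer seed.
#' @return a `base_learner_spec`.
#' @export
base_learner_spec <- function(kind, params = list(), grid = NULL, seed = 1L) {
  if (!kind %in% LEARNER_KINDS) stop_masegc("spec", "unknown learner kind '%s'", kind)
  structure(list(kind = kind, params = params,
                 grid = grid %||% default_grid(kind), seed = as.integer(seed)),
            class = "base_learner_spec")
}

#' Default specs for the five base learners
#' @param seed integer seed fanned out per learner.
#' @return named list of [base_learner_spec] objects.
#' @export
default_learner_specs <- function(seed = 1L) {
  specs <- lapply(LEARNER_KINDS, function(k) {
    base_learner_spec(k, seed = derive_seed(seed, paste0("learner_", k)))
  })
  names(specs) <- LEARNER_KINDS
  specs
}

#' Fit a base learner
#'
#' @param spec a [base_learner_spec].
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1).
#' @param params hyperparameters overriding `spec$params`.
#' @return a fitted learner honouring [predict_proba].
#' @export
fit_learner <- function(spec, X, y, params = NULL) {
  stopifnot(inherits(spec, "base_learner_spec"))
  p <- utils::modifyList(spec$params, as.list(params %||% list()))
  y <- as.integer(y)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- with_seed(spec$seed, switch(
    spec$kind,
    svm_rbf = e1071::svm(X, yf, kernel = "radial",
                         cost = p$cost %||% 0.1, gamma = p$gamma %||% 1,
                         probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(X, yf, ntree = p$ntree %||% 500L),
    decision_tree = {
      df <- data.frame(.y = yf, X)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = p$cp %||% 0.01,
                                                  minsplit = p$minsplit %||% 20L,
                                                  xval = 0L))
    },
    adaboost = fit_adaboost(X, y, n_estimators = p$n_estimators %||% 100L),
    cnn1d = fit_cnn1d(X, y,
                      filters = p$filters %||% c(16L, 32L),
                      kernel = p$kernel %||% 3L,
                      dropout = p$dropout %||% 0.3,
                      epochs = p$epochs %||% 40L,
                      lr = p$lr %||% 0.01,
                      batch_size = p$batch_size %||% 32L,
                      seed = spec$seed)))
  structure(list(kind = spec$kind, fit = fit, params = p, seed = spec$seed),
            class = c(paste0("fitted_", spec$kind), "fitted_learner"))
}

#' Class-probability predictions of a fitted base learner
#'
#' @param object a fitted learner from [fit_learner].
#' @param X numeric matrix, samples x features.
#' @return matrix with columns `"0"` and `"1"`, rows summing to 1.
#' @export
predict_proba <- function(object, X) {
  stopifnot(inherits(object, "fitted_learner"))
  pr <- switch(object$kind,
    svm_rbf = {
      pred <- stats::predict(object$fit, X, probability = TRUE)
      att <- attr(pred, "probabilities")
      if (is.null(att)) {  # degenerate probability model: fall back to decision values
        dv <- attr(stats::predict(object$fit, X, decision.values = TRUE), "decision.values")
        p1 <- stats::plogis(as.numeric(dv) * ifelse(object$fit$labels[1L] == 2, 1, -1))
        cbind("0" = 1 - p1, "1" = p1)
      } else att[, c("0", "1"), drop = FALSE]
    },
    random_forest = stats::predict(object$fit, X, type = "prob")[, c("0", "1"), drop = FALSE],
    decision_tree = stats::predict(object$fit, data.frame(X), type = "prob")[, c("0", "1"), drop = FALSE],
    adaboost = predict_adaboost(object$fit, X),
    cnn1d = predict_cnn1d(object$fit, X))
  pr <- pmin(pmax(pr, 0), 1)
  dimnames(pr) <- list(NULL, c("0", "1"))
  pr
}

# ---- AdaBoost (discrete, depth-1 rpart stumps) ------------------------------

fit_adaboost <- function(X, y, n_estimators = 100L) {
  n <- nrow(X)
  ypm <- ifelse(y == 1L, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(y, levels = c(0L, 1L)), X)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1L, cp = -1,
                                                      minsplit = 2L, xval = 0L))
    pred <- ifelse(stats::predict(st, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != ypm))
    if (err <= 1e-12) {        # perfect stump: dominate and stop
      stumps[[m]] <- st; alphas[m] <- 10; break
    }
    if (err >= 0.5) break      # no better than chance: stop adding
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- st; alphas[m] <- alpha
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {  # fall back to the class prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(fit, X) {
  n <- nrow(X)
  if (length(fit$stumps) == 0L) {
    p1 <- rep(fit$prior, n)
    return(cbind("0" = 1 - p1, "1" = p1))
  }
  df <- data.frame(X)
  score <- rep(0, n)
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    score <- score + fit$alphas[m] * pred
  }
  p1 <- stats::plogis(2 * score)  # logistic map of the additive margin
  cbind("0" = 1 - p1, "1" = p1)
}
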