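# Preprocessing: zero-abundance filtering, KNN imputation, min-max scaling,
# and a moderated-t differential screen with Benjamini-Hochberg adjustment.
#
# Stage order is filter -> impute -> scale -> screen; the pipeline runner
# enforces it and fits scaling/screening statistics on training samples
# only (a global "paper mode" reproducing pre-split scaling is available).

#' Remove low-abundance features
#'
#' Drops every feature whose fraction of exact zeros is strictly greater
#' than `zero_fraction_threshold` ("more than 60%" by default); features at
#' exactly the threshold are retained. Row order is preserved.
#'
#' @param matrix an [omics_matrix] without missing entries (zeros among
#'   observed values only).
#' @param zero_fraction_threshold removal threshold, default 0.6.
#' @return the filtered [omics_matrix]; the dropped ids are attached as
#'   attribute `"dropped"`.
#' @export
filter_low_abundance <- function(matrix, zero_fraction_threshold = 0.6) {
  stopifnot(inherits(matrix, "omics_matrix"))
  zf <- rowMeans(matrix$values == 0, na.rm = TRUE)
  keep <- zf <= zero_fraction_threshold
  if (!any(keep)) stop_masegc("empty_result", "zero filter removed every feature")
  out <- omics_matrix(matrix$values[keep, , drop = FALSE], matrix$modality)
  attr(out, "dropped") <- rownames(matrix$values)[!keep]
  out
}

# Missing-aware distance between sample columns a and b of v:
# root mean squared difference over co-observed features.
sample_distances <- function(v, s) {
  n <- ncol(v)
  obs_s <- !is.na(v[, s])
  d <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    if (j == s) next
    co <- obs_s & !is.na(v[, j])
    nc <- sum(co)
    if (nc == 0L) next
    d[j] <- sqrt(sum((v[co, s] - v[co, j])^2) / nc)
  }
  d
}

#' Impute missing entries by k-nearest neighbours
#'
#' Each missing entry (feature f, sample s) is replaced by the mean of f
#' over the k samples nearest to s. Distance between two samples is the
#' Euclidean distance over features observed in both, normalized by the
#' co-observed count, so samples with different missingness patterns are
#' comparable. Observed entries are untouched.
#'
#' @param matrix an [omics_matrix].
#' @param k neighbour count, default 5.
#' @return a complete [omics_matrix].
#' @export
knn_impute <- function(matrix, k = 5L) {
  stopifnot(inherits(matrix, "omics_matrix"))
  v <- matrix$values
  if (!anyNA(v)) return(matrix)
  all_missing <- rownames(v)[rowSums(!is.na(v)) == 0L]
  if (length(all_missing)) {
    stop_masegc("imputation", "feature(s) missing in every sample: %s",
                paste(all_missing, collapse = ", "))
  }
  miss_cols <- which(colSums(is.na(v)) > 0L)
  out <- v
  for (s in miss_cols) {
    d <- sample_distances(v, s)
    if (all(is.na(d))) {
      stop_masegc("distance", "sample '%s' shares no observed feature with any other sample",
                  colnames(v)[s])
    }
    miss_f <- which(is.na(v[, s]))
    for (f in miss_f) {
      cand <- which(!is.na(v[f, ]) & !is.na(d))
      if (length(cand) < k) {
        stop_masegc("imputation", "fewer than k=%d usable neighbours for feature '%s'",
                    k, rownames(v)[f])
      }
      nn <- cand[order(d[cand], cand)][seq_len(k)]
      out[f, s] <- mean(v[f, nn])
    }
  }
  omics_matrix(out, matrix$modality)
}

#' Learn per-feature min-max scaling statistics
#'
#' @param matrix a complete [omics_matrix] (a training split).
#' @return a `scaling_stats` object with per-feature min and max.
#' @export
fit_minmax <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (anyNA(matrix$values)) stop_masegc("format", "impute before scaling")
  structure(list(feature_ids = rownames(matrix$values),
                 min = apply(matrix$values, 1L, min),
                 max = apply(matrix$values, 1L, max)),
            class = "scaling_stats")
}

#' Apply min-max scaling statistics
#'
#' Affine per-feature map to `[0, 1]` using training min/max; values from
#' new data outside the training range are clipped to the unit interval.
#' Constant features map to 0.
#'
#' @param matrix a complete [omics_matrix].
#' @param stats a `scaling_stats` fitted with [fit_minmax].
#' @return the scaled [omics_matrix].
#' @export
apply_minmax <- function(matrix, stats) {
  stopifnot(inherits(matrix, "omics_matrix"), inherits(stats, "scaling_stats"))
  if (!identical(rownames(matrix$values), stats$feature_ids)) {
    stop_masegc("mismatch", "scaling stats fitted on a different feature set")
  }
  rng <- stats$max - stats$min
  v <- (matrix$values - stats$min) / ifelse(rng == 0, 1, rng)
  v[rng == 0, ] <- 0
  v <- pmin(pmax(v, 0), 1)
  omics_matrix(v, matrix$modality)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sort p-values ascending, compute p_(i) * m / i, enforce monotonicity by
#' cumulative minimum from the largest rank down, cap at 1, and return the
#' adjusted values in the original order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_masegc("domain", "p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  adj <- numeric(m)
  adj[ord] <- q
  adj
}

# Newton inversion of the trigamma function (for the variance-prior df).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated two-group t screen
#'
#' Per feature, a two-sample t-statistic whose pooled variance is shrunk
#' toward a common prior: the prior degrees of freedom d0 and prior
#' variance s0^2 are estimated by method of moments on the log sample
#' variances (trigamma inversion), the posterior variance is
#' (d0 s0^2 + d s^2) / (d0 + d), and p-values come from a t distribution
#' with d + d0 degrees of freedom. Adjustment is Benjamini-Hochberg;
#' a feature is selected when its adjusted p-value is below `alpha`.
#' Features constant across all samples get p = 1.
#'
#' @param matrix a normalized, complete [omics_matrix].
#' @param labels a [label_table] covering the matrix samples.
#' @param alpha selection threshold on the adjusted p-value, default 0.001.
#' @return a `screen_result` data.frame: feature, p, adj_p, selected, t.
#' @export
moderated_differential_screen <- function(matrix, labels, alpha = 0.001) {
  stopifnot(inherits(matrix, "omics_matrix"), inherits(labels, "label_table"))
  v <- matrix$values
  y <- labels$labels[colnames(v)]
  if (anyNA(y)) stop_masegc("mismatch", "labels missing for some samples")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop_masegc("dof", "each class needs at least 2 samples")
  g1 <- v[, y == 1L, drop = FALSE]; g0 <- v[, y == 0L, drop = FALSE]
  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  ss <- rowSums((g1 - m1)^2) + rowSums((g0 - m0)^2)
  d <- n1 + n0 - 2L
  s2 <- ss / d
  pos <- s2 > 0
  if (!any(pos)) {
    # every feature constant: nothing testable
    adj <- rep(1, nrow(v))
    return(screen_df(rownames(v), rep(1, nrow(v)), adj, alpha, rep(0, nrow(v))))
  }
  z <- log(s2[pos])
  evar <- if (length(z) >= 2L) stats::var(z) - trigamma(d / 2) else 0
  evar <- max(evar, 0)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  }
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  df_total <- d + d0
  tval <- (m1 - m0) / sqrt(s2_post * (1 / n1 + 1 / n0))
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  zero_var_zero_diff <- s2 == 0 & (m1 - m0) == 0
  p[zero_var_zero_diff] <- 1
  tval[zero_var_zero_diff] <- 0
  screen_df(rownames(v), p, benjamini_hochberg(p), alpha, tval)
}

screen_df <- function(ids, p, adj, alpha, tval) {
  structure(data.frame(feature = ids, p = p, adj_p = adj,
                       selected = adj < alpha, t = tval,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("screen_result", "data.frame"), alpha = alpha)
}

#' Preprocess one modality (filter, impute, scale, screen)
#'
#' Convenience runner enforcing the stage order on a single modality.
#' The zero filter applies to expression modalities only by default
#' (methylation beta values are rarely exactly zero).
#'
#' @param matrix an [omics_matrix].
#' @param labels a [label_table] (used by the screen).
#' @param zero_fraction_threshold passed to [filter_low_abundance].
#' @param knn_k passed to [knn_impute].
#' @param alpha passed to [moderated_differential_screen];
#'   `NA` skips screening.
#' @param filter_modalities modalities subject to the zero filter.
#' @return list with `matrix` (scaled, screened-selected features),
#'   `stats` (scaling_stats), `screen` (screen_result or NULL).
#' @export
preprocess_modality <- function(matrix, labels, zero_fraction_threshold = 0.6,
                                knn_k = 5L, alpha = 0.001,
                                filter_modalities = EXPRESSION_MODALITIES) {
  m <- matrix
  if (m$modality %in% filter_modalities) {
    m <- filter_low_abundance(m, zero_fraction_threshold)
  }
  m <- knn_impute(m, knn_k)
  st <- fit_minmax(m)
  m <- apply_minmax(m, st)
  scr <- NULL
  if (!is.na(alpha)) {
    scr <- moderated_differential_screen(m, labels, alpha)
    keep <- scr$feature[scr$selected]
    if (length(keep) == 0L) keep <- scr$feature[order(scr$adj_p)][1L]  # keep best feature
    m <- omics_matrix(m$values[keep, , drop = FALSE], m$modality)
  }
  list(matrix = m, stats = st, screen = scr)
}
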