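# Hybrid class balancing: SMOTE oversampling of the minority class
# followed by Tomek-link removal of boundary samples.
#
# Matrices here are samples x features (classifier orientation). All
# synthetic points are convex combinations of two minority originals;
# after cleaning, re-running the link finder on the retained set returns
# no links.

euclid_dist_matrix <- function(X) {
  as.matrix(stats::dist(X, method = "euclidean"))
}

#' SMOTE oversampling of the minority class
#'
#' Synthetic minority samples `s = x + u * (x_nn - x)` are added, where
#' `x` is a minority sample, `x_nn` one of its `k` nearest minority
#' neighbours (Euclidean) and `u ~ Uniform(0, 1)`, until the
#' minority/majority ratio reaches `target_ratio`.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary labels (0/1), one per row.
#' @param k neighbour count among minority samples, default 5.
#' @param target_ratio desired minority/majority ratio, default 1.
#' @param seed integer seed.
#' @return a `resampled_dataset`: list with `X`, `y`, `provenance`
#'   (`"original"`/`"synthetic"`), `removed` (empty here).
#' @export
smote_oversample <- function(X, y, k = 5L, target_ratio = 1.0, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (tab[["1"]] < tab[["0"]]) 1L else 0L
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min < 2L) stop_masegc("parameter", "minority class needs at least 2 samples")
  if (n_min <= k) stop_masegc("parameter", "minority size %d must exceed k = %d", n_min, k)
  n_target <- round(target_ratio * n_maj)
  n_new <- n_target - n_min
  if (n_new <= 0L) {
    warning("class ratio already meets target; no synthetic samples added")
    return(structure(list(X = X, y = y,
                          provenance = rep("original", nrow(X)),
                          removed = data.frame(index = integer(0), reason = character(0))),
                     class = "resampled_dataset"))
  }
  idx_min <- which(y == minority)
  Xm <- X[idx_min, , drop = FALSE]
  dm <- euclid_dist_matrix(Xm)
  diag(dm) <- Inf
  nn_idx <- matrix(0L, nrow(Xm), k)
  for (i in seq_len(nrow(Xm))) nn_idx[i, ] <- order(dm[i, ])[seq_len(k)]
  with_seed(seed, {
    base <- sample(seq_len(nrow(Xm)), n_new, replace = TRUE)
    pick <- sample(seq_len(k), n_new, replace = TRUE)
    u <- stats::runif(n_new)
    syn <- Xm[base, , drop = FALSE] +
      u * (Xm[nn_idx[cbind(base, pick)], , drop = FALSE] - Xm[base, , drop = FALSE])
    rownames(syn) <- sprintf("syn%04d", seq_len(n_new))
    structure(list(X = rbind(X, syn),
                   y = c(y, rep(minority, n_new)),
                   provenance = c(rep("original", nrow(X)), rep("synthetic", n_new)),
                   removed = data.frame(index = integer(0), reason = character(0))),
              class = "resampled_dataset")
  })
}

#' Find Tomek links
#'
#' Returns every pair of opposite-class samples that are mutual single
#' nearest neighbours under Euclidean distance. Distance ties are broken
#' in favour of the lowest sample index.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary labels.
#' @return two-column integer matrix of row-index pairs (a < b), zero rows
#'   when no link exists.
#' @export
find_tomek_links <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_masegc("parameter", "both classes required")
  n <- nrow(X)
  d <- euclid_dist_matrix(X)
  diag(d) <- Inf
  # lowest index wins ties: which.min returns the first minimum
  nn <- apply(d, 1L, which.min)
  links <- matrix(integer(0), ncol = 2L)
  for (a in seq_len(n)) {
    b <- nn[a]
    if (b > a && nn[b] == a && y[a] != y[b]) {
      links <- rbind(links, c(a, b))
    }
  }
  colnames(links) <- c("a", "b")
  links
}

#' SMOTE followed by Tomek-link removal
#'
#' Oversamples the minority class, then repeatedly detects Tomek links on
#' the augmented set and removes them per `removal_policy` until the
#' retained set contains none.
#'
#' @inheritParams smote_oversample
#' @param removal_policy `"both"` removes both members of a link
#'   (boundary cleaning); `"majority_only"` removes only the
#'   majority-class member.
#' @return a `resampled_dataset` with `removed` recording dropped samples.
#' @export
smote_tomek <- function(X, y, k = 5L, target_ratio = 1.0, seed = 1L,
                        removal_policy = c("both", "majority_only")) {
  removal_policy <- match.arg(removal_policy)
  # majority defined on the original labels (post-SMOTE counts may tie)
  majority <- if (sum(y == 1L) >= sum(y == 0L)) 1L else 0L
  rs <- smote_oversample(X, y, k = k, target_ratio = target_ratio, seed = seed)
  keep <- seq_len(nrow(rs$X))
  removed_idx <- integer(0)
  repeat {
    Xk <- rs$X[keep, , drop = FALSE]
    yk <- rs$y[keep]
    if (length(unique(yk)) < 2L) break
    links <- find_tomek_links(Xk, yk)
    if (nrow(links) == 0L) break
    drop_local <- if (removal_policy == "both") {
      unique(as.vector(links))
    } else {
      maj_member <- ifelse(yk[links[, 1L]] == majority, links[, 1L], links[, 2L])
      unique(maj_member)
    }
    removed_idx <- c(removed_idx, keep[drop_local])
    keep <- keep[-drop_local]
  }
  structure(list(X = rs$X[keep, , drop = FALSE],
                 y = rs$y[keep],
                 provenance = rs$provenance[keep],
                 removed = data.frame(index = removed_idx,
                                      reason = rep("tomek", length(removed_idx)))),
            class = "resampled_dataset")
}

#' @export
print.resampled_dataset <- function(x, ...) {
  cat(sprintf("<resampled_dataset> %d samples (%d tumor / %d normal), %d synthetic, %d removed\n",
              nrow(x$X), sum(x$y == 1L), sum(x$y == 0L),
              sum(x$provenance == "synthetic"), nrow(x$removed)))
  invisible(x)
}
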