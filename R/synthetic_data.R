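# Synthetic multi-omics generator with known class structure.
#
# A shared latent-factor model drives all modalities so that cross-modal
# fusion genuinely helps: class labels shift the means of the informative
# shared factors, each modality observes the shared factors (plus a few
# modality-private ones) through its own loading matrix, and a per-modality
# transform reproduces the marginal quirks the pipeline must survive —
# non-negative zero-inflated expression values and bounded methylation
# beta values with missing entries.

#' Build a simulation configuration
#'
#' @param n_samples_per_class integer pair `c(tumor, normal)`.
#' @param feature_dims named integer vector of feature counts per modality
#'   (default exon 60, mrna 50, mirna 30, methylation 40 at fixture scale).
#' @param n_latent_factors number of shared latent factors.
#' @param class_effect_size mean shift of informative factors between the
#'   classes, in factor standard-deviation units.
#' @param noise_sd standard deviation of additive feature noise.
#' @param zero_inflation_rate Bernoulli zeroing rate on expression values.
#' @param missing_rate Bernoulli masking rate on methylation values.
#' @param informative_fraction fraction of shared factors carrying the
#'   class shift.
#' @param n_private_factors modality-private factors (no class signal) so
#'   no single modality is sufficient on its own.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_class = c(200L, 40L),
                              feature_dims = c(exon = 60L, mrna = 50L,
                                               mirna = 30L, methylation = 40L),
                              n_latent_factors = 6L,
                              class_effect_size = 3,
                              noise_sd = 1,
                              zero_inflation_rate = 0.15,
                              missing_rate = 0.05,
                              informative_fraction = 0.5,
                              n_private_factors = 2L,
                              seed = 1L) {
  cfg <- list(n_samples_per_class = as.integer(n_samples_per_class),
              feature_dims = feature_dims, n_latent_factors = as.integer(n_latent_factors),
              class_effect_size = class_effect_size, noise_sd = noise_sd,
              zero_inflation_rate = zero_inflation_rate, missing_rate = missing_rate,
              informative_fraction = informative_fraction,
              n_private_factors = as.integer(n_private_factors), seed = as.integer(seed))
  if (length(cfg$n_samples_per_class) != 2L || any(cfg$n_samples_per_class < 0L) ||
      sum(cfg$n_samples_per_class) == 0L || all(cfg$n_samples_per_class == 0L) ||
      any(cfg$n_samples_per_class == 0L)) {
    stop_masegc("config", "both classes need at least one sample")
  }
  if (cfg$zero_inflation_rate < 0 || cfg$zero_inflation_rate >= 1 ||
      cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_masegc("config", "rates must lie in [0, 1)")
  }
  if (cfg$informative_fraction <= 0 || cfg$informative_fraction > 1) {
    stop_masegc("config", "informative_fraction must lie in (0, 1]")
  }
  if (cfg$noise_sd <= 0) stop_masegc("config", "noise_sd must be positive")
  if (any(cfg$feature_dims < cfg$n_latent_factors)) {
    stop_masegc("config", "every modality needs at least n_latent_factors features")
  }
  class(cfg) <- "simulation_config"
  cfg
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Simulate a multi-omics dataset with ground truth
#'
#' Per sample a shared factor vector is drawn N(mu_class, I); informative
#' factors differ in mean by `class_effect_size` between classes. Each
#' modality is loadings x (shared + private factors) + N(0, noise_sd^2)
#' noise, then passed through its modality transform: expression modalities
#' through softplus (non-negative, right-skewed) with Bernoulli zeroing,
#' methylation through a logistic squash to (0, 1) with Bernoulli masking.
#'
#' @param config a [simulation_config].
#' @return list with `dataset` (a `multiomics_dataset`) and `truth`
#'   (labels, informative factor indices, informative feature ids and
#'   loadings per modality).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n1 <- config$n_samples_per_class[1L]  # tumor
    n0 <- config$n_samples_per_class[2L]  # normal
    n <- n1 + n0
    ids <- sprintf("S%03d", seq_len(n))
    y <- c(rep(1L, n1), rep(0L, n0))
    k <- config$n_latent_factors
    kp <- config$n_private_factors
    n_inf <- max(1L, ceiling(config$informative_fraction * k))
    inf_idx <- seq_len(n_inf)
    mu <- matrix(0, n, k)
    mu[y == 1L, inf_idx] <- config$class_effect_size / 2
    mu[y == 0L, inf_idx] <- -config$class_effect_size / 2
    fac <- mu + matrix(stats::rnorm(n * k), n, k)

    mats <- list(); truth_feats <- list(); loadings <- list()
    for (mod in names(config$feature_dims)) {
      p <- config$feature_dims[[mod]]
      priv <- matrix(stats::rnorm(n * kp), n, kp)
      # block loadings: each signal feature loads on exactly one shared
      # factor with magnitude bounded away from zero, so every feature
      # marked informative in the ground truth carries a real net class
      # shift (dense loadings would let shifts cancel across factors);
      # the other half of the features load only on private factors
      lshared <- matrix(0, k, p)
      n_noise_feats <- floor(p / 2)
      signal_cols <- seq_len(p - n_noise_feats)
      owner <- rep_len(seq_len(k), length(signal_cols))
      mag <- stats::runif(length(signal_cols), 1, 2) *
        sample(c(-1, 1), length(signal_cols), replace = TRUE)
      lshared[cbind(owner, signal_cols)] <- mag
      lpriv <- matrix(stats::rnorm(p * kp, sd = 1), kp, p)
      raw <- fac %*% lshared + priv %*% lpriv +
        matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
      fids <- sprintf("%s_f%04d", mod, seq_len(p))
      informative <- fids[colSums(abs(lshared[inf_idx, , drop = FALSE])) > 0]
      if (mod == "methylation") {
        v <- 1 / (1 + exp(-raw / 2))
        if (config$missing_rate > 0) {
          mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
          v[mask] <- NA_real_
        }
      } else {
        v <- softplus(raw)
        if (config$zero_inflation_rate > 0) {
          zmask <- matrix(stats::runif(n * p) < config$zero_inflation_rate, n, p)
          v[zmask] <- 0
        }
      }
      vt <- t(v)  # features x samples
      dimnames(vt) <- list(fids, ids)
      mats[[mod]] <- omics_matrix(vt, mod)
      truth_feats[[mod]] <- informative
      loadings[[mod]] <- lshared
    }
    dataset <- align_samples(mats, label_table(ids, y))
    truth <- list(labels = stats::setNames(y, ids),
                  informative_factors = inf_idx,
                  informative_features = truth_feats,
                  loadings = loadings, seed = config$seed)
    list(dataset = dataset, truth = truth)
  })
}

#' Mask entries of a matrix at random
#'
#' Each entry is independently set to missing with probability `rate`;
#' used to exercise the imputation path on otherwise complete data.
#'
#' @param matrix an [omics_matrix] with no missing entries.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return an [omics_matrix] with the mask applied.
#' @export
inject_missingness <- function(matrix, rate, seed) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (anyNA(matrix$values)) stop_masegc("config", "matrix already has missing entries")
  if (rate < 0 || rate >= 1) stop_masegc("config", "rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  with_seed(seed, {
    v <- matrix$values
    mask <- matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v))
    v[mask] <- NA_real_
    omics_matrix(v, matrix$modality)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits one Xena-style TSV per modality, a labels TSV and a ground-truth
#' JSON (informative feature ids and seed).
#'
#' @param sim result of [simulate_multiomics].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mod in names(sim$dataset$modalities)) {
    write_omics_matrix(sim$dataset$modalities[[mod]], file.path(dir, paste0(mod, ".tsv")))
  }
  write_label_table(sim$dataset$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(list(informative_features = sim$truth$informative_features,
                            informative_factors = sim$truth$informative_factors,
                            seed = sim$truth$seed),
                       file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
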