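# Shared fixtures, generated in code.

tiny_matrix <- function(modality = "mrna", nf = 3L, ns = 2L, seed = 1L) {
  v <- matrix(seq_len(nf * ns) / 2, nf, ns,
              dimnames = list(sprintf("g%d", seq_len(nf)), sprintf("s%d", seq_len(ns))))
  masegc::omics_matrix(v, modality)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Two well-separated Gaussian blobs, samples x features.
blob_data <- function(n1 = 30L, n0 = 30L, d = 4L, sep = 6, seed = 1L, sd = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n1 * d, mean = sep / 2, sd = sd), n1, d),
             matrix(stats::rnorm(n0 * d, mean = -sep / 2, sd = sd), n0, d))
  list(X = X, y = c(rep(1L, n1), rep(0L, n0)))
}

small_sim <- function(seed = 5L, n = c(40L, 15L), effect = 3) {
  masegc::simulate_multiomics(masegc::simulation_config(
    n_samples_per_class = n, class_effect_size = effect, seed = seed))
}

fast_config <- function(seed = 3L) {
  rc <- masegc::default_run_config(seed = seed)
  rc$outer_folds <- 3L
  rc$inner_folds <- 3L
  rc$ae_epochs <- 20L
  rc$alpha <- 0.05  # screen threshold appropriate for ~50-sample fixtures
  rc$learner_params$cnn1d$epochs <- 10L
  rc$learner_params$adaboost$n_estimators <- 20L
  rc$learner_params$random_forest$ntree <- 100L
  rc
}
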