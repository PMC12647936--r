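test_that("the zero filter removes strictly-above-threshold features only", {
  v <- rbind(c(rep(0, 7), 1, 2, 3),   # 0.7 zero fraction -> removed
             c(rep(0, 6), 1, 2, 3, 4), # exactly 0.6 -> retained
             1:10)                     # no zeros -> retained
  dimnames(v) <- list(c("g70", "g60", "g00"), sprintf("s%d", 1:10))
  out <- filter_low_abundance(omics_matrix(v, "mrna"), 0.6)
  expect_identical(rownames(out$values), c("g60", "g00"))
  expect_identical(attr(out, "dropped"), "g70")
  expect_error(filter_low_abundance(omics_matrix(v[1L, , drop = FALSE], "mrna"), 0.5),
               class = "masegc_empty_result")
})

test_that("knn imputation matches hand-derived neighbours and bounds", {
  # s1 identical to s2 on observed features; k=1 copies s2's value of g3
  v <- rbind(g1 = c(1, 1, 9), g2 = c(2, 2, 9), g3 = c(NA, 5, 7))
  colnames(v) <- c("s1", "s2", "s3")
  out <- knn_impute(omics_matrix(v, "methylation"), k = 1L)
  expect_equal(out$values["g3", "s1"], 5)
  # observed entries untouched
  expect_identical(out$values[!is.na(v)], v[!is.na(v)])

  # constant matrix: imputed value equals the constant
  vc <- matrix(3, 4L, 5L, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  vc[2L, 3L] <- NA
  outc <- knn_impute(omics_matrix(vc, "methylation"), k = 2L)
  expect_equal(outc$values[2L, 3L], 3)

  # no missing entries: identity
  m <- tiny_matrix()
  expect_identical(knn_impute(m)$values, m$values)

  # imputed values stay within the observed range of their feature
  sim <- small_sim(seed = 8L, n = c(15L, 10L))
  meth <- sim$dataset$modalities$methylation
  imp <- knn_impute(meth, k = 3L)
  rng <- t(apply(meth$values, 1L, range, na.rm = TRUE))
  expect_true(all(imp$values >= rng[, 1L] - 1e-12 & imp$values <= rng[, 2L] + 1e-12))
})

test_that("knn imputation errors are specific", {
  v <- rbind(g1 = c(NA, NA, NA), g2 = c(1, 2, 3))
  colnames(v) <- paste0("s", 1:3)
  err <- expect_error(knn_impute(omics_matrix(v, "methylation")), class = "masegc_imputation")
  expect_match(conditionMessage(err), "g1")
})

test_that("min-max scaling maps to [0,1], clips new data, zeroes constants", {
  v <- rbind(g1 = c(0, 5, 10), g2 = c(3, 3, 3))
  colnames(v) <- paste0("s", 1:3)
  m <- omics_matrix(v, "mrna")
  st <- fit_minmax(m)
  sc <- apply_minmax(m, st)
  expect_equal(unname(sc$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(sc$values["g2", ]), c(0, 0, 0))

  # new data beyond the training range clips to [0, 1]
  vn <- rbind(g1 = c(-2, 12), g2 = c(3, 4))
  colnames(vn) <- c("t1", "t2")
  scn <- apply_minmax(omics_matrix(vn, "mrna"), st)
  expect_equal(unname(scn$values["g1", ]), c(0, 1))

  # rank order is preserved (affine per feature)
  set.seed(1)
  vr <- matrix(stats::rnorm(50), 5L, 10L,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  mr <- omics_matrix(vr, "mrna")
  scr <- apply_minmax(mr, fit_minmax(mr))
  for (i in 1:5) expect_identical(order(scr$values[i, ]), order(vr[i, ]))

  expect_error(apply_minmax(tiny_matrix(), st), class = "masegc_mismatch")
})

test_that("benjamini_hochberg matches the hand-derived step-up values", {
  expect_equal(benjamini_hochberg(c(0.001, 0.01, 0.02, 0.9)),
               c(0.004, 0.02, 0.02666666666666667, 0.9), tolerance = 1e-12)
  expect_equal(benjamini_hochberg(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "masegc_domain")
})

test_that("benjamini_hochberg agrees with stats::p.adjust on random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1L))^sample(1:3, 1L)
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("the moderated screen flags separated features and not constants", {
  set.seed(17)
  n <- 40L
  v <- rbind(
    sep = c(stats::rnorm(20, 10), stats::rnorm(20, 0)),  # well separated
    flat = rep(2, n),                                     # constant
    null1 = stats::rnorm(n), null2 = stats::rnorm(n), null3 = stats::rnorm(n))
  colnames(v) <- paste0("s", seq_len(n))
  lab <- label_table(colnames(v), rep(c(1L, 0L), each = 20L))
  scr <- moderated_differential_screen(omics_matrix(v, "mrna"), lab, alpha = 0.001)
  expect_true(scr$selected[scr$feature == "sep"])
  expect_lt(scr$adj_p[scr$feature == "sep"], 0.001)
  expect_equal(scr$p[scr$feature == "flat"], 1)
  expect_false(scr$selected[scr$feature == "flat"])
  expect_true(all(scr$adj_p >= scr$p - 1e-15))
  expect_error(moderated_differential_screen(omics_matrix(v[, 1:3], "mrna"),
                                             label_table(paste0("s", 1:3), c(1L, 0L, 0L))),
               class = "masegc_dof")
})

test_that("the screen's type-I error is near nominal under the null", {
  set.seed(31)
  n <- 30L; m <- 1000L
  v <- matrix(stats::rnorm(m * n), m, n,
              dimnames = list(sprintf("g%04d", 1:m), sprintf("s%02d", 1:n)))
  lab <- label_table(colnames(v), sample(rep(c(0L, 1L), each = 15L)))
  scr <- moderated_differential_screen(omics_matrix(v, "mrna"), lab, alpha = 0.001)
  expect_lte(sum(scr$selected), 5L)
})

test_that("moderated t p-values track limma's eBayes on shared data", {
  skip_if_not_installed("limma")
  set.seed(23)
  n1 <- 12L; n0 <- 10L; m <- 200L
  v <- matrix(stats::rnorm(m * (n1 + n0)), m)
  v[1:20, 1:n1] <- v[1:20, 1:n1] + 2
  dimnames(v) <- list(sprintf("g%03d", 1:m), sprintf("s%02d", 1:(n1 + n0)))
  y <- c(rep(1L, n1), rep(0L, n0))
  design <- cbind(1, y)
  fit <- limma::eBayes(limma::lmFit(v, design))
  ours <- moderated_differential_screen(omics_matrix(v, "mrna"),
                                        label_table(colnames(v), y), alpha = 0.001)
  expect_gt(stats::cor(-log10(ours$p), -log10(fit$p.value[, 2L])), 0.99)
  # same features land in the tail
  expect_setequal(ours$feature[rank(ours$p) <= 20], rownames(v)[rank(fit$p.value[, 2L]) <= 20])
})

test_that("preprocess_modality enforces filter -> impute -> scale -> screen", {
  sim <- small_sim(seed = 3L, n = c(20L, 12L))
  lab <- sim$dataset$labels
  res <- preprocess_modality(sim$dataset$modalities$methylation, lab, alpha = 0.05)
  expect_false(anyNA(res$matrix$values))
  expect_true(all(res$matrix$values >= 0 & res$matrix$values <= 1))
  expect_true(all(res$matrix$modality == "methylation"))
  expect_s3_class(res$screen, "screen_result")
  expect_true(all(rownames(res$matrix$values) %in% res$screen$feature))
})
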