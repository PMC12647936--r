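make_manual_model <- function(W, b, acts) {
  # single-layer encoder with hand-set weights, identity-style decoder
  cfg <- train_config(latent_dim = ncol(W), hidden = integer(0),
                      hidden_activation = acts, latent_activation = acts,
                      output_activation = "linear", seed = 1L)
  m <- autoencoder_model(nrow(W), cfg)
  m$W[[1L]] <- W; m$b[[1L]] <- b
  m
}

test_that("encode applies sigma(W'z + b) layer by layer", {
  # identity linear layer reproduces the input
  m <- make_manual_model(diag(2), c(0, 0), "linear")
  X <- matrix(c(1, 2, -3, 4), 2L, 2L)
  expect_equal(encode(m, X), X)

  # sigmoid with zero weights gives 0.5 everywhere
  ms <- make_manual_model(matrix(0, 2L, 2L), c(0, 0), "sigmoid")
  expect_true(all(encode(ms, X) == 0.5))

  # 2-layer net against a hand-propagated value
  cfg <- train_config(latent_dim = 2L, hidden = 2L, hidden_activation = "relu",
                      latent_activation = "relu", seed = 1L)
  m2 <- autoencoder_model(2L, cfg)
  m2$W[[1L]] <- matrix(c(1, -1, 0.5, 2), 2L, 2L); m2$b[[1L]] <- c(0.1, -0.2)
  m2$W[[2L]] <- matrix(c(2, 0, 1, 1), 2L, 2L); m2$b[[2L]] <- c(0, 0.3)
  h <- pmax(c(1, 1) %*% m2$W[[1L]] + m2$b[[1L]], 0)
  out <- pmax(h %*% m2$W[[2L]] + m2$b[[2L]], 0)
  expect_equal(encode(m2, matrix(c(1, 1), 1L)), out)

  expect_error(encode(m, matrix(1, 1L, 3L)), class = "masegc_dimension")
})

test_that("an untied linear decoder can invert a linear encoder on low-rank data", {
  set.seed(3)
  # rank-2 data in 5 dims
  B <- matrix(stats::rnorm(10), 5L, 2L)
  X <- matrix(stats::rnorm(40), 20L, 2L) %*% t(B)
  cfg <- train_config(latent_dim = 2L, hidden = integer(0),
                      hidden_activation = "linear", latent_activation = "linear",
                      output_activation = "linear", seed = 1L)
  m <- autoencoder_model(5L, cfg)
  W <- matrix(stats::rnorm(10), 5L, 2L)
  m$W[[1L]] <- W; m$b[[1L]] <- c(0, 0)
  # decoder = pseudo-inverse of the encoder restricted to the data span
  Z <- X %*% W
  m$Wd[[1L]] <- qr.solve(crossprod(Z), crossprod(Z, X))
  m$bd[[1L]] <- rep(0, 5L)
  expect_lt(max(abs(decode(m, encode(m, X)) - X)), 1e-6)
  # decode(encode(X)) preserves shape for any valid model
  expect_identical(dim(decode(m, encode(m, X))), dim(X))
  expect_error(decode(m, matrix(1, 1L, 3L)), class = "masegc_dimension")
})

test_that("reconstruction loss divides by the sample count only", {
  X <- matrix(c(1, 0), 1L, 2L)
  expect_equal(reconstruction_loss(X, matrix(0, 1L, 2L)), 1)
  # residual norms^2 of 1 and 3 average to 2
  expect_equal(reconstruction_loss(rbind(c(1, 0), c(sqrt(3), 0)),
                                   matrix(0, 2L, 2L)), 2)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_error(reconstruction_loss(X, matrix(0, 2L, 2L)), class = "masegc_dimension")
})

test_that("joint loss and fusion share the convex-weight contract", {
  expect_equal(joint_loss(c(1, 2, 3, 4), rep(0.25, 4L)), 2.5)
  expect_equal(joint_loss(c(7, 1, 1, 1), c(1, 0, 0, 0)), 7)
  expect_equal(joint_loss(rep(3, 4L), c(0.1, 0.2, 0.3, 0.4)), 3)
  expect_error(joint_loss(1:4, c(0.5, 0.5, 0.5, 0.5)), class = "masegc_constraint")
  expect_error(joint_loss(1:2, c(0.7, 0.2)), class = "masegc_constraint")

  expect_equal(fuse_latents(list(matrix(c(1, 0), 1L)), 1), matrix(c(1, 0), 1L))
  expect_equal(fuse_latents(list(matrix(c(1, 0), 1L, 2L), matrix(c(0, 1), 1L, 2L)),
                            c(0.25, 0.75)),
               matrix(c(0.25, 0.75), 1L, 2L))
  Zs <- replicate(4L, matrix(stats::rnorm(6), 2L, 3L), simplify = FALSE)
  expect_equal(fuse_latents(rep(Zs[1L], 4L), c(0.1, 0.2, 0.3, 0.4)), Zs[[1L]])
  expect_error(fuse_latents(list(matrix(0, 1L, 2L), matrix(0, 1L, 3L)), c(0.5, 0.5)),
               class = "masegc_fusion")
})

test_that("fusion is linear and permutation-commutative under uniform weights", {
  set.seed(8)
  Zs <- replicate(4L, matrix(stats::rnorm(12), 3L, 4L), simplify = FALSE)
  Zs2 <- replicate(4L, matrix(stats::rnorm(12), 3L, 4L), simplify = FALSE)
  w <- c(0.4, 0.3, 0.2, 0.1)
  lhs <- fuse_latents(Map(function(a, b) 2 * a + 5 * b, Zs, Zs2), w)
  rhs <- 2 * fuse_latents(Zs, w) + 5 * fuse_latents(Zs2, w)
  expect_equal(lhs, rhs)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(fuse_latents(Zs, rep(0.25, 4L)), fuse_latents(Zs[perm], rep(0.25, 4L)))
})

test_that("training reduces the loss on representable low-rank signal", {
  set.seed(5)
  u <- stats::runif(40); v <- stats::runif(10)
  X <- u %*% t(v)  # rank-1, values in [0,1]
  cfg <- train_config(epochs = 200L, lr = 5e-3, latent_dim = 1L, seed = 2L)
  m <- train_autoencoder(X, cfg)
  trace <- attr(m, "loss_trace")
  expect_length(trace, 201L)
  expect_true(all(is.finite(trace)))
  expect_lt(trace[length(trace)], 0.05 * trace[1L])
  expect_lte(trace[length(trace)], trace[1L])
})

test_that("0-epoch training returns the initialized model; seeds reproduce", {
  X <- matrix(stats::runif(60), 10L, 6L)
  cfg0 <- train_config(epochs = 0L, latent_dim = 2L, seed = 9L)
  m0 <- train_autoencoder(X, cfg0)
  expect_length(attr(m0, "loss_trace"), 1L)

  cfg <- train_config(epochs = 15L, latent_dim = 2L, seed = 9L)
  m1 <- train_autoencoder(X, cfg)
  m2 <- train_autoencoder(X, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$Wd, m2$Wd)
})

test_that("tied decoders reuse transposed encoder weights", {
  X <- matrix(stats::runif(60), 10L, 6L)
  cfg <- train_config(epochs = 10L, latent_dim = 2L, seed = 4L, tied = TRUE)
  m <- train_autoencoder(X, cfg)
  expect_null(m$Wd)
  expect_identical(dim(masegc:::decoder_weight(m, 1L)), c(2L, 8L))
  expect_true(all(is.finite(attr(m, "loss_trace"))))
})
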