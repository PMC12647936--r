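# Modality-specific autoencoders and weighted latent fusion.
#
# Each modality gets its own multi-layer autoencoder: the encoder applies
# sigma(W'z + b) layer by layer down to the shared latent width, the
# decoder mirrors the encoder (untied weights by default; a tied flag
# reuses the transposed encoder weights), and training minimises the
# per-sample mean squared reconstruction error
#   L = (1/n) sum_i || x_i - xhat_i ||^2
# (divide by the sample count only, not the feature count) with Adam.
# The joint multi-modality loss is the convex combination
# sum_i lambda_i L_i with lambda_i >= 0, sum lambda_i = 1, and the fused
# representation uses the same weights: Z = sum_i lambda_i Z_i.
#
# Matrices are samples x features throughout this module.

ACTIVATIONS <- list(
  relu = list(f = function(x) pmax(x, 0), df = function(x, a) (x > 0) * 1),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)), df = function(x, a) a * (1 - a)),
  tanh = list(f = tanh, df = function(x, a) 1 - a^2),
  linear = list(f = identity, df = function(x, a) 1)
)

#' Training configuration for an autoencoder
#'
#' @param epochs training epochs (0 returns the initialized model).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed integer seed (initialization + batch shuffling).
#' @param hidden widths of encoder hidden layers between input and latent;
#'   default one hidden layer of `4 * latent_dim`.
#' @param latent_dim latent width (shared across modalities for fusion).
#' @param hidden_activation activation of hidden layers.
#' @param latent_activation activation of the bottleneck layer; linear by
#'   default so the latent space is unconstrained.
#' @param output_activation decoder output activation; sigmoid matches
#'   min-max scaled inputs.
#' @param tied reuse transposed encoder weights in the decoder.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, lr = 1e-3, batch_size = 32L, seed = 1L,
                         hidden = NULL, latent_dim = 8L,
                         hidden_activation = "relu",
                         latent_activation = "linear",
                         output_activation = "sigmoid", tied = FALSE) {
  stopifnot(epochs >= 0, lr > 0, batch_size >= 1, latent_dim >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 hidden = hidden, latent_dim = as.integer(latent_dim),
                 hidden_activation = match.arg(hidden_activation, names(ACTIVATIONS)),
                 latent_activation = match.arg(latent_activation, names(ACTIVATIONS)),
                 output_activation = match.arg(output_activation, names(ACTIVATIONS)),
                 tied = isTRUE(tied)),
            class = "train_config")
}

#' Build an (untrained) autoencoder model
#'
#' Layer widths run input -> hidden... -> latent for the encoder and are
#' mirrored for the decoder. Weights are Glorot-uniform initialized.
#'
#' @param input_dim feature count of the modality.
#' @param config a [train_config].
#' @param modality modality tag.
#' @return an `autoencoder_model`.
#' @export
autoencoder_model <- function(input_dim, config, modality = "fused") {
  hidden <- config$hidden %||% (4L * config$latent_dim)
  enc_dims <- c(input_dim, hidden, config$latent_dim)
  dec_dims <- rev(enc_dims)
  n_enc <- length(enc_dims) - 1L
  acts_enc <- c(rep(config$hidden_activation, n_enc - 1L),
                config$latent_activation %||% "linear")
  acts_dec <- c(rep(config$hidden_activation, n_enc - 1L), config$output_activation)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  with_seed(config$seed, {
    W <- lapply(seq_len(n_enc), function(l) glorot(enc_dims[l], enc_dims[l + 1L]))
    b <- lapply(seq_len(n_enc), function(l) rep(0, enc_dims[l + 1L]))
    if (config$tied) {
      Wd <- NULL
    } else {
      Wd <- lapply(seq_len(n_enc), function(l) glorot(dec_dims[l], dec_dims[l + 1L]))
    }
    bd <- lapply(seq_len(n_enc), function(l) rep(0, dec_dims[l + 1L]))
    structure(list(modality = modality, W = W, b = b, Wd = Wd, bd = bd,
                   acts_enc = acts_enc, acts_dec = acts_dec,
                   dims = enc_dims, latent_dim = config$latent_dim,
                   tied = config$tied, config = config),
              class = "autoencoder_model")
  })
}

#' Encode samples to the latent space
#'
#' @param model an `autoencoder_model`.
#' @param X numeric matrix, samples x features; width must equal the model
#'   input width.
#' @return latent matrix, samples x latent_dim.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "autoencoder_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$dims[1L]) {
    stop_masegc("dimension", "input width %d != model input width %d",
                ncol(X), model$dims[1L])
  }
  Z <- X
  for (l in seq_along(model$W)) {
    Z <- ACTIVATIONS[[model$acts_enc[l]]]$f(sweep(Z %*% model$W[[l]], 2L, model$b[[l]], "+"))
  }
  Z
}

decoder_weight <- function(model, l) {
  if (model$tied) t(model$W[[length(model$W) - l + 1L]]) else model$Wd[[l]]
}

#' Decode latent codes back to feature space
#'
#' @param model an `autoencoder_model`.
#' @param Z latent matrix, samples x latent_dim.
#' @return reconstruction matrix, samples x features.
#' @export
decode <- function(model, Z) {
  stopifnot(inherits(model, "autoencoder_model"))
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != model$latent_dim) {
    stop_masegc("dimension", "latent width %d != model latent width %d",
                ncol(Z), model$latent_dim)
  }
  A <- Z
  for (l in seq_along(model$bd)) {
    A <- ACTIVATIONS[[model$acts_dec[l]]]$f(sweep(A %*% decoder_weight(model, l), 2L, model$bd[[l]], "+"))
  }
  A
}

#' Mean squared reconstruction loss
#'
#' Mean over samples of the squared Euclidean norm of the per-sample
#' residual (divides by the sample count only). Set
#' `per_feature = TRUE` for the per-entry-normalized variant.
#'
#' @param X input matrix, samples x features.
#' @param X_rec reconstruction, same shape.
#' @param per_feature also divide by the feature count.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_rec, per_feature = FALSE) {
  if (!identical(dim(X), dim(X_rec))) stop_masegc("dimension", "shape mismatch")
  l <- sum((X - X_rec)^2) / nrow(X)
  if (per_feature) l <- l / ncol(X)
  l
}

check_fusion_weights <- function(weights, M) {
  if (length(weights) != M) stop_masegc("constraint", "need %d weights", M)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_masegc("constraint", "fusion weights must be non-negative and sum to 1")
  }
  invisible(weights)
}

#' Weighted joint reconstruction loss across modalities
#'
#' @param losses per-modality reconstruction losses.
#' @param weights convex weights (non-negative, sum 1 within 1e-9).
#' @return weighted sum.
#' @export
joint_loss <- function(losses, weights) {
  check_fusion_weights(weights, length(losses))
  sum(losses * weights)
}

#' Fuse per-modality latent codes by convex combination
#'
#' `Z = sum_i lambda_i Z_i` with the same weights as the joint loss.
#'
#' @param latents list of latent matrices with identical shapes.
#' @param weights convex weights.
#' @return the fused latent matrix.
#' @export
fuse_latents <- function(latents, weights) {
  check_fusion_weights(weights, length(latents))
  dims <- lapply(latents, dim)
  if (length(unique(dims)) != 1L) {
    stop_masegc("fusion", "latent matrices must share dimensions (equal latent_dim)")
  }
  Z <- latents[[1L]] * weights[1L]
  for (i in seq_along(latents)[-1L]) Z <- Z + latents[[i]] * weights[i]
  Z
}

#' Bundle per-modality latents with their fusion
#'
#' @param latents named list of latent matrices (samples x latent_dim).
#' @param weights convex fusion weights, one per modality.
#' @return a `latent_bundle` with `latents`, `weights` and fused `Z`.
#' @export
latent_bundle <- function(latents, weights) {
  Z <- fuse_latents(latents, weights)
  structure(list(latents = latents, weights = weights, Z = Z),
            class = "latent_bundle")
}

ae_forward <- function(model, X) {
  pre_e <- list(); act_e <- list(A0 = X)
  A <- X
  for (l in seq_along(model$W)) {
    P <- sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+")
    A <- ACTIVATIONS[[model$acts_enc[l]]]$f(P)
    pre_e[[l]] <- P; act_e[[l + 1L]] <- A
  }
  pre_d <- list(); act_d <- list(A)
  for (l in seq_along(model$bd)) {
    P <- sweep(A %*% decoder_weight(model, l), 2L, model$bd[[l]], "+")
    A <- ACTIVATIONS[[model$acts_dec[l]]]$f(P)
    pre_d[[l]] <- P; act_d[[l + 1L]] <- A
  }
  list(pre_e = pre_e, act_e = act_e, pre_d = pre_d, act_d = act_d, X_rec = A)
}

#' Train an autoencoder by Adam on the reconstruction loss
#'
#' Deterministic given `config$seed`; the loss trace (initial loss plus one
#' entry per epoch) is attached to the returned model. Training aborts
#' with an error carrying the trace if the loss becomes non-finite.
#'
#' @param X training matrix, samples x features, scaled to `[0, 1]`.
#' @param config a [train_config].
#' @param modality modality tag stored on the model.
#' @return a fitted `autoencoder_model` with attribute `loss_trace`.
#' @export
train_autoencoder <- function(X, config, modality = "fused") {
  stopifnot(is.matrix(X), inherits(config, "train_config"))
  model <- autoencoder_model(ncol(X), config, modality)
  n <- nrow(X)
  trace <- reconstruction_loss(X, decode(model, encode(model, X)))
  if (config$epochs == 0L) {
    attr(model, "loss_trace") <- trace
    return(model)
  }
  # Adam state per parameter group
  params <- c(model$W, if (!model$tied) model$Wd, model$b, model$bd)
  nW <- length(model$W); nWd <- if (model$tied) 0L else length(model$Wd)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        bidx <- idx[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[bidx, , drop = FALSE]
        fw <- ae_forward(model, Xb)
        nb <- nrow(Xb)
        # dL/dX_rec for L = (1/nb) sum ||x - xhat||^2
        delta <- 2 * (fw$X_rec - Xb) / nb
        gW <- vector("list", nW); gWd <- vector("list", max(nWd, nW))
        gb <- vector("list", nW); gbd <- vector("list", nW)
        # decoder backward
        for (l in rev(seq_along(model$bd))) {
          a <- fw$act_d[[l + 1L]]
          delta <- delta * ACTIVATIONS[[model$acts_dec[l]]]$df(fw$pre_d[[l]], a)
          gWd[[l]] <- crossprod(fw$act_d[[l]], delta)
          gbd[[l]] <- colSums(delta)
          delta <- delta %*% t(decoder_weight(model, l))
        }
        # encoder backward
        for (l in rev(seq_along(model$W))) {
          a <- fw$act_e[[l + 1L]]
          delta <- delta * ACTIVATIONS[[model$acts_enc[l]]]$df(fw$pre_e[[l]], a)
          gW[[l]] <- crossprod(fw$act_e[[l]], delta)
          gb[[l]] <- colSums(delta)
          delta <- delta %*% t(model$W[[l]])
        }
        if (model$tied) {
          # tied decoder layer l shares W[n_enc - l + 1]: add transposed grads
          for (l in seq_along(model$bd)) {
            le <- length(model$W) - l + 1L
            gW[[le]] <- gW[[le]] + t(gWd[[l]])
          }
          grads <- c(gW, gb, gbd)
        } else {
          grads <- c(gW, gWd[seq_len(nWd)], gb, gbd)
        }
        t_step <- t_step + 1L
        for (j in seq_along(grads)) {
          mstate[[j]] <- beta1 * mstate[[j]] + (1 - beta1) * grads[[j]]
          vstate[[j]] <- beta2 * vstate[[j]] + (1 - beta2) * grads[[j]]^2
          mhat <- mstate[[j]] / (1 - beta1^t_step)
          vhat <- vstate[[j]] / (1 - beta2^t_step)
          upd <- config$lr * mhat / (sqrt(vhat) + eps)
          if (j <= nW) {
            model$W[[j]] <- model$W[[j]] - upd
          } else if (j <= nW + nWd) {
            model$Wd[[j - nW]] <- model$Wd[[j - nW]] - upd
          } else if (j <= nW + nWd + nW) {
            model$b[[j - nW - nWd]] <- model$b[[j - nW - nWd]] - as.vector(upd)
          } else {
            model$bd[[j - nW - nWd - nW]] <- model$bd[[j - nW - nWd - nW]] - as.vector(upd)
          }
        }
      }
      l_ep <- reconstruction_loss(X, decode(model, encode(model, X)))
      if (!is.finite(l_ep)) {
        cond <- errorCondition("autoencoder training diverged (non-finite loss)",
                               class = c("masegc_training", "masegc_error"))
        cond$trace <- c(trace, l_ep)
        stop(cond)
      }
      trace <- c(trace, l_ep)
    }
  })
  attr(model, "loss_trace") <- trace
  model
}

#' Train one autoencoder per modality and fuse the latents
#'
#' @param mats named list of [omics_matrix] (features x samples); each is
#'   transposed internally to samples x features.
#' @param config a [train_config]; per-modality seeds are derived from
#'   `config$seed` and the modality name.
#' @param weights fusion weights, default uniform `1/M`.
#' @return list with `models` (per modality) and `bundle`
#'   (a [latent_bundle] over the training samples).
#' @export
train_multiomics_autoencoders <- function(mats, config, weights = NULL) {
  M <- length(mats)
  weights <- weights %||% rep(1 / M, M)
  check_fusion_weights(weights, M)
  models <- list(); latents <- list()
  for (mod in names(mats)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("ae_", mod))
    X <- t(mats[[mod]]$values)
    models[[mod]] <- train_autoencoder(X, cfg, modality = mod)
    latents[[mod]] <- encode(models[[mod]], X)
  }
  list(models = models, bundle = latent_bundle(latents, weights))
}

#' Encode new samples with fitted per-modality autoencoders
#'
#' The models are frozen: no per-sample adaptation happens here.
#'
#' @param models named list of fitted autoencoder models.
#' @param mats named list of [omics_matrix] with matching feature sets.
#' @param weights fusion weights.
#' @return a [latent_bundle] for the new samples.
#' @export
encode_multiomics <- function(models, mats, weights = NULL) {
  M <- length(models)
  weights <- weights %||% rep(1 / M, M)
  latents <- lapply(names(models), function(mod) encode(models[[mod]], t(mats[[mod]]$values)))
  names(latents) <- names(models)
  latent_bundle(latents, weights)
}
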