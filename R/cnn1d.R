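# 1-D convolutional network over the fused latent vector.
#
# The latent code is treated as a length-d single-channel sequence. Two
# valid-mode conv blocks (kernel 3; 16 then 32 filters by default), each
# ReLU + max-pool-2 where the sequence is long enough, then inverted
# dropout, a dense 2-way layer and softmax, trained with Adam on the
# cross-entropy. Written as plain array code: at latent-fixture scale
# (d around 8-64) this is fast without any deep-learning runtime.

conv1d_forward <- function(A, W, b) {
  # A: n x L x C ; W: k x C x F ; returns n x (L-k+1) x F
  n <- dim(A)[1L]; L <- dim(A)[2L]; C <- dim(A)[3L]
  k <- dim(W)[1L]; f <- dim(W)[3L]
  Lout <- L - k + 1L
  out <- array(rep(b, each = n * Lout), dim = c(n, Lout, f))
  for (j in seq_len(k)) {
    Aj <- matrix(A[, j:(j + Lout - 1L), , drop = FALSE], n * Lout, C)
    Wj <- matrix(W[j, , ], C, f)
    out <- out + array(Aj %*% Wj, dim = c(n, Lout, f))
  }
  out
}

conv1d_backward <- function(A, W, dOut) {
  n <- dim(A)[1L]; L <- dim(A)[2L]; C <- dim(A)[3L]
  k <- dim(W)[1L]; f <- dim(W)[3L]
  Lout <- dim(dOut)[2L]
  dW <- array(0, dim = dim(W))
  dA <- array(0, dim = dim(A))
  dOutM <- matrix(dOut, n * Lout, f)
  for (j in seq_len(k)) {
    Aj <- matrix(A[, j:(j + Lout - 1L), , drop = FALSE], n * Lout, C)
    dW[j, , ] <- crossprod(Aj, dOutM)
    dAj <- dOutM %*% t(matrix(W[j, , ], C, f))          # (n*Lout) x C
    dA[, j:(j + Lout - 1L), ] <- dA[, j:(j + Lout - 1L), , drop = FALSE] +
      array(dAj, dim = c(n, Lout, C))
  }
  list(dW = dW, db = colSums(dOutM), dA = dA)
}

maxpool2_forward <- function(A) {
  L <- dim(A)[2L]
  Lout <- L %/% 2L
  a1 <- A[, seq(1L, 2L * Lout, by = 2L), , drop = FALSE]
  a2 <- A[, seq(2L, 2L * Lout, by = 2L), , drop = FALSE]
  take_first <- a1 >= a2
  list(out = ifelse(take_first, a1, a2), take_first = take_first, Lin = L)
}

maxpool2_backward <- function(pool, dOut) {
  d1 <- dOut * pool$take_first
  d2 <- dOut * !pool$take_first
  Lout <- dim(dOut)[2L]
  dA <- array(0, dim = c(dim(dOut)[1L], pool$Lin, dim(dOut)[3L]))
  dA[, seq(1L, 2L * Lout, by = 2L), ] <- d1
  dA[, seq(2L, 2L * Lout, by = 2L), ] <- d2
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

cnn_arch <- function(d, filters, kernel) {
  layers <- list(); L <- d; C <- 1L
  for (f in filters) {
    if (L < kernel) break
    layers[[length(layers) + 1L]] <- list(type = "conv", k = kernel, cin = C, f = f)
    L <- L - kernel + 1L; C <- f
    if (L >= 2L) {
      layers[[length(layers) + 1L]] <- list(type = "pool")
      L <- L %/% 2L
    }
  }
  list(layers = layers, flat = L * C, L = L, C = C)
}

cnn_forward <- function(net, X, training = FALSE, dropmask = NULL) {
  n <- nrow(X)
  A <- array(X, dim = c(n, ncol(X), 1L))
  cache <- list()
  for (i in seq_along(net$arch$layers)) {
    ly <- net$arch$layers[[i]]
    if (ly$type == "conv") {
      pre <- conv1d_forward(A, net$W[[i]], net$b[[i]])
      cache[[i]] <- list(A_in = A, pre = pre)
      A <- pmax(pre, 0)
    } else {
      pool <- maxpool2_forward(A)
      cache[[i]] <- pool
      A <- pool$out
    }
  }
  flat <- matrix(A, n, net$arch$flat)
  if (training && net$dropout > 0) {
    flat <- flat * dropmask / (1 - net$dropout)
  }
  logits <- sweep(flat %*% net$Wd, 2L, net$bd, "+")
  list(cache = cache, flat = flat, prob = softmax_rows(logits))
}

fit_cnn1d <- function(X, y, filters = c(16L, 32L), kernel = 3L, dropout = 0.3,
                      epochs = 40L, lr = 0.01, batch_size = 32L, seed = 1L) {
  d <- ncol(X); n <- nrow(X)
  arch <- cnn_arch(d, filters, kernel)
  with_seed(seed, {
    W <- list(); b <- list()
    for (i in seq_along(arch$layers)) {
      ly <- arch$layers[[i]]
      if (ly$type == "conv") {
        lim <- sqrt(6 / (ly$k * ly$cin + ly$f))
        W[[i]] <- array(stats::runif(ly$k * ly$cin * ly$f, -lim, lim),
                        dim = c(ly$k, ly$cin, ly$f))
        b[[i]] <- rep(0, ly$f)
      } else { W[i] <- list(NULL); b[i] <- list(NULL) }
    }
    lim <- sqrt(6 / (arch$flat + 2))
    net <- list(arch = arch, W = W, b = b,
                Wd = matrix(stats::runif(arch$flat * 2, -lim, lim), arch$flat, 2L),
                bd = rep(0, 2L), dropout = dropout)
    Y <- cbind(1 - y, y)  # one-hot, column 2 = tumor
    conv_ids <- which(vapply(arch$layers, function(l) l$type == "conv", logical(1)))
    zeros_like <- function(x) if (is.null(x)) NULL else x * 0
    mW <- lapply(net$W, zeros_like); vW <- lapply(net$W, zeros_like)
    mb <- lapply(net$b, zeros_like); vb <- lapply(net$b, zeros_like)
    mWd <- net$Wd * 0; vWd <- mWd; mbd <- net$bd * 0; vbd <- mbd
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]; Yb <- Y[bi, , drop = FALSE]
        nb <- length(bi)
        dropmask <- if (dropout > 0) {
          matrix(stats::runif(nb * arch$flat) >= dropout, nb, arch$flat)
        } else NULL
        fw <- cnn_forward(net, Xb, training = TRUE, dropmask = dropmask)
        dlogits <- (fw$prob - Yb) / nb
        gWd <- crossprod(fw$flat, dlogits)
        gbd <- colSums(dlogits)
        dflat <- dlogits %*% t(net$Wd)
        if (dropout > 0) dflat <- dflat * dropmask / (1 - dropout)
        dA <- array(dflat, dim = c(nb, arch$L, arch$C))
        gW <- lapply(net$W, zeros_like); gb <- lapply(net$b, zeros_like)
        for (i in rev(seq_along(arch$layers))) {
          ly <- arch$layers[[i]]
          if (ly$type == "pool") {
            dA <- maxpool2_backward(fw$cache[[i]], dA)
          } else {
            dA <- dA * (fw$cache[[i]]$pre > 0)
            bk <- conv1d_backward(fw$cache[[i]]$A_in, net$W[[i]], dA)
            gW[[i]] <- bk$dW; gb[[i]] <- bk$db
            dA <- bk$dA
          }
        }
        t_step <- t_step + 1L
        adam <- function(p, g, m, v) {
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          p <- p - lr * (m / (1 - b1^t_step)) / (sqrt(v / (1 - b2^t_step)) + eps)
          list(p = p, m = m, v = v)
        }
        for (i in conv_ids) {
          u <- adam(net$W[[i]], gW[[i]], mW[[i]], vW[[i]])
          net$W[[i]] <- u$p; mW[[i]] <- u$m; vW[[i]] <- u$v
          u <- adam(net$b[[i]], gb[[i]], mb[[i]], vb[[i]])
          net$b[[i]] <- u$p; mb[[i]] <- u$m; vb[[i]] <- u$v
        }
        u <- adam(net$Wd, gWd, mWd, vWd); net$Wd <- u$p; mWd <- u$m; vWd <- u$v
        u <- adam(net$bd, gbd, mbd, vbd); net$bd <- u$p; mbd <- u$m; vbd <- u$v
      }
    }
    net
  })
}

predict_cnn1d <- function(net, X) {
  pr <- cnn_forward(net, X, training = FALSE)$prob
  colnames(pr) <- c("0", "1")
  pr
}
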