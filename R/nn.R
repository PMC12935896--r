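# Fully connected classification network: input -> 256 -> 128 -> 64 ->
# softmax, ReLU activations, He initialization, batch normalization and
# dropout on the first two hidden layers, L2 penalty on the second hidden
# layer's weights. Trained with Adam on minibatches, an early-stopping
# validation slice, and learning-rate halving on validation plateaus.
# Written directly in base R matrix algebra; the data are small (hundreds
# to low thousands of rows, 9 features), so vectorized BLAS calls suffice.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden, n_out)
  L <- length(dims) - 1
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
      dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- rep(0, dims[l + 1])
  }
  # batch-norm affine parameters + running stats for hidden layers 1 and 2
  for (l in 1:2) {
    params[[paste0("gamma", l)]] <- rep(1, dims[l + 1])
    params[[paste0("beta", l)]] <- rep(0, dims[l + 1])
    params[[paste0("rmu", l)]] <- rep(0, dims[l + 1])
    params[[paste0("rvar", l)]] <- rep(1, dims[l + 1])
  }
  params
}

.bn_eps <- 1e-5

# Forward pass. training=TRUE uses batch statistics (updating running
# stats) and applies inverted dropout with the supplied masks.
mlp_forward <- function(params, X, training = FALSE, dropout = 0.3,
                        masks = NULL, bn_momentum = 0.9) {
  cache <- list(A0 = X)
  A <- X
  for (l in 1:3) {
    Z <- sweep(A %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]], "+")
    if (l <= 2) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        params[[paste0("rmu", l)]] <-
          bn_momentum * params[[paste0("rmu", l)]] + (1 - bn_momentum) * mu
        params[[paste0("rvar", l)]] <-
          bn_momentum * params[[paste0("rvar", l)]] + (1 - bn_momentum) * v
      } else {
        mu <- params[[paste0("rmu", l)]]
        v <- params[[paste0("rvar", l)]]
      }
      Zhat <- sweep(sweep(Z, 2, mu), 2, sqrt(v + .bn_eps), "/")
      Y <- sweep(sweep(Zhat, 2, params[[paste0("gamma", l)]], "*"), 2,
                 params[[paste0("beta", l)]], "+")
      cache[[paste0("Z", l)]] <- Z
      cache[[paste0("Zhat", l)]] <- Zhat
      cache[[paste0("mu", l)]] <- mu
      cache[[paste0("var", l)]] <- v
    } else Y <- Z
    A <- relu(Y)
    cache[[paste0("Y", l)]] <- Y
    if (training && l <= 2) {
      A <- A * masks[[l]]
      cache[[paste0("mask", l)]] <- masks[[l]]
    }
    cache[[paste0("A", l)]] <- A
  }
  Z4 <- sweep(A %*% params$W4, 2, params$b4, "+")
  cache$P <- softmax_rows(Z4)
  cache$params <- params
  cache
}

# Backward pass for the mean cross-entropy loss; returns gradients named
# like the parameters. l2 penalizes W2 only.
mlp_backward <- function(params, cache, Y_onehot, l2) {
  m <- nrow(Y_onehot)
  grads <- list()
  dZ <- (cache$P - Y_onehot) / m
  grads$W4 <- t(cache$A3) %*% dZ
  grads$b4 <- colSums(dZ)
  dA <- dZ %*% t(params$W4)
  for (l in 3:1) {
    if (l <= 2) dA <- dA * cache[[paste0("mask", l)]]
    dY <- dA * (cache[[paste0("Y", l)]] > 0)
    if (l <= 2) {
      Zhat <- cache[[paste0("Zhat", l)]]
      v <- cache[[paste0("var", l)]]
      inv_sd <- 1 / sqrt(v + .bn_eps)
      grads[[paste0("gamma", l)]] <- colSums(dY * Zhat)
      grads[[paste0("beta", l)]] <- colSums(dY)
      dZhat <- sweep(dY, 2, params[[paste0("gamma", l)]], "*")
      mb <- nrow(dY)
      dZ <- sweep(dZhat -
                    matrix(colMeans(dZhat), mb, ncol(dZhat), byrow = TRUE) -
                    sweep(Zhat, 2, colMeans(dZhat * Zhat), "*"),
                  2, inv_sd, "*")
    } else dZ <- dY
    A_prev <- cache[[paste0("A", l - 1)]]
    grads[[paste0("W", l)]] <- t(A_prev) %*% dZ
    grads[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(params[[paste0("W", l)]])
  }
  grads$W2 <- grads$W2 + l2 * params$W2
  grads
}

cross_entropy <- function(P, Y_onehot) {
  -mean(rowSums(Y_onehot * log(pmax(P, 1e-12))))
}

# Train the network. X is the (already scaled) feature matrix, y an integer
# vector of class indices 1..K. Deterministic given `seed`.
mlp_train <- function(X, y, n_classes, hidden = c(256L, 128L, 64L),
                      dropout = 0.3, l2 = 1e-4, lr = 1e-3, batch_size = 32L,
                      max_epochs = 500L, patience = 30L, lr_patience = 10L,
                      val_fraction = 0.1, seed = 1L) {
  stopifnot(length(hidden) == 3)
  n <- nrow(X)
  with_seed(seed, {
    n_val <- max(1L, round(n * val_fraction))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    onehot <- function(yy) {
      M <- matrix(0, length(yy), n_classes)
      M[cbind(seq_along(yy), yy)] <- 1
      M
    }
    Ytr <- onehot(ytr); Yval <- onehot(yval)
    params <- mlp_init(ncol(X), hidden, n_classes)
    pnames <- grep("^(W|b|gamma|beta)", names(params), value = TRUE)
    adam_m <- lapply(params[pnames], function(p) p * 0)
    adam_v <- adam_m
    t_step <- 0
    best <- list(loss = Inf, params = params, epoch = 0)
    stall <- 0; lr_stall <- 0
    cur_lr <- lr
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(length(tr_idx))
      for (start in seq(1, length(perm), by = batch_size)) {
        bi <- perm[start:min(start + batch_size - 1, length(perm))]
        if (length(bi) < 2) next  # batch norm needs >= 2 rows
        masks <- lapply(1:2, function(l)
          matrix(stats::rbinom(length(bi) * hidden[l], 1, 1 - dropout) /
                   (1 - dropout), length(bi), hidden[l]))
        cache <- mlp_forward(params, Xtr[bi, , drop = FALSE], training = TRUE,
                             dropout = dropout, masks = masks)
        params[c("rmu1", "rvar1", "rmu2", "rvar2")] <-
          cache$params[c("rmu1", "rvar1", "rmu2", "rvar2")]
        grads <- mlp_backward(params, cache, Ytr[bi, , drop = FALSE], l2)
        t_step <- t_step + 1
        for (pn in pnames) {
          g <- grads[[pn]]
          adam_m[[pn]] <- 0.9 * adam_m[[pn]] + 0.1 * g
          adam_v[[pn]] <- 0.999 * adam_v[[pn]] + 0.001 * g^2
          mhat <- adam_m[[pn]] / (1 - 0.9^t_step)
          vhat <- adam_v[[pn]] / (1 - 0.999^t_step)
          params[[pn]] <- params[[pn]] - cur_lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      val_P <- mlp_forward(params, Xval, training = FALSE)$P
      val_loss <- cross_entropy(val_P, Yval)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        stall <- 0; lr_stall <- 0
      } else {
        stall <- stall + 1; lr_stall <- lr_stall + 1
        if (lr_stall >= lr_patience) { cur_lr <- cur_lr / 2; lr_stall <- 0 }
        if (stall >= patience) break
      }
    }
    structure(list(params = best$params, n_classes = n_classes,
                   hidden = hidden, best_epoch = best$epoch,
                   val_loss = best$loss),
              class = "mlp_model")
  })
}

mlp_predict_proba <- function(model, X) {
  mlp_forward(model$params, X, training = FALSE)$P
}
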