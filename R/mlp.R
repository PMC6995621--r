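# Internal fully connected network: forward pass, backpropagation and adam
# updates in plain matrix arithmetic. Inputs, targets and all state are
# plain numeric matrices; the training loop is deterministic given a seed.

mlpInit <- function(arch, seed) {
  nc <- length(arch) - 1L
  withSeed(seed, {
    W <- vector("list", nc)
    b <- vector("list", nc)
    for (l in seq_len(nc)) {
      # He initialization for ReLU hidden layers
      W[[l]] <- matrix(stats::rnorm(arch[l] * arch[l + 1L]) *
                         sqrt(2 / arch[l]), arch[l], arch[l + 1L])
      b[[l]] <- numeric(arch[l + 1L])
    }
    list(W = W, b = b)
  })
}

# X: n x d matrix. Returns list of post-activation matrices per layer.
mlpForward <- function(params, X) {
  nc <- length(params$W)
  acts <- vector("list", nc + 1L)
  acts[[1L]] <- X
  for (l in seq_len(nc)) {
    z <- acts[[l]] %*% params$W[[l]]
    z <- sweep(z, 2L, params$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < nc) pmax(z, 0) else z
  }
  acts
}

mlpPredict <- function(params, X) {
  drop(mlpForward(params, X)[[length(params$W) + 1L]])
}

# Mean-squared-error loss and its gradients for one mini-batch.
mlpGrad <- function(params, X, y) {
  nc <- length(params$W)
  acts <- mlpForward(params, X)
  n <- nrow(X)
  pred <- acts[[nc + 1L]]
  err <- pred - y                       # n x 1
  loss <- mean(err^2)
  gW <- vector("list", nc)
  gb <- vector("list", nc)
  delta <- 2 * err / n
  for (l in seq(nc, 1L)) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$W[[l]])) * (acts[[l]] > 0)
  }
  list(gW = gW, gb = gb, loss = loss)
}

adamInit <- function(params) {
  list(mW = lapply(params$W, function(w) w * 0),
       vW = lapply(params$W, function(w) w * 0),
       mb = lapply(params$b, function(b) b * 0),
       vb = lapply(params$b, function(b) b * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(params$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    params$b[[l]] <- params$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Mini-batch training loop with early stopping on the mean epoch loss.
mlpTrain <- function(X, y, arch, learningRate = 0.001, batchSize = 4L,
                     epochs = 2000L, seed = 1L, patience = 100L,
                     minDelta = 1e-9) {
  params <- mlpInit(arch, seed)
  state <- adamInit(params)
  n <- nrow(X)
  y <- matrix(y, ncol = 1L)
  lossTrace <- numeric(0)
  bestLoss <- Inf
  wait <- 0L
  withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        g <- mlpGrad(params, X[idx, , drop = FALSE],
                     y[idx, , drop = FALSE])
        upd <- adamStep(params, g, state, lr = learningRate)
        params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + g$loss
        nb <- nb + 1L
      }
      lossTrace[ep] <- epochLoss / nb
      if (lossTrace[ep] < bestLoss - minDelta) {
        bestLoss <- lossTrace[ep]
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  list(params = params, lossTrace = lossTrace)
}
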