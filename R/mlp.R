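# Minimal fully connected feed-forward network with ReLU hidden units,
# trained by minibatch Adam on mean-squared error. Written with plain
# matrix algebra; the networks involved are small (a few thousand
# weights), so BLAS-backed %*% is ample.

mlp_init <- function(layer_sizes) {
  n_layers <- length(layer_sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_sizes[l]
    fan_out <- layer_sizes[l + 1L]
    if (l < n_layers) {
      # He (fan-in scaled) init for ReLU hidden layers.
      W[[l]] <- matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                       nrow = fan_in)
      b[[l]] <- numeric(fan_out)
    } else {
      # Output head starts at the prior mean (weights 0, bias 1/K): the
      # head is then symmetric under permutation of the output units, so
      # relabelling mixture components permutes the whole training
      # trajectory exactly.
      W[[l]] <- matrix(0, nrow = fan_in, ncol = fan_out)
      b[[l]] <- rep(1 / fan_out, fan_out)
    }
  }
  list(W = W, b = b)
}

mlp_forward <- function(params, X, keep = FALSE) {
  n_layers <- length(params$W)
  A <- X
  acts <- if (keep) vector("list", n_layers + 1L)
  if (keep) acts[[1L]] <- A
  for (l in seq_len(n_layers)) {
    Z <- A %*% params$W[[l]]
    Z <- sweep(Z, 2, params$b[[l]], "+")
    A <- if (l < n_layers) pmax(Z, 0) else Z
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# Forward + backward pass; returns per-parameter gradients of the mean
# squared error (mean over batch rows and output units, as in the usual
# MSE-loss convention) plus the loss value.
mlp_grad <- function(params, X, Y) {
  n_layers <- length(params$W)
  fw <- mlp_forward(params, X, keep = TRUE)
  err <- fw$out - Y
  loss <- mean(err^2)
  delta <- 2 * err / length(err)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    A_prev <- fw$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (fw$acts[[l]] > 0)
    }
  }
  list(gW = gW, gb = gb, loss = loss)
}

adam_init <- function(params) {
  zero_like <- function(x) lapply(x, function(p) p * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
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

# Minibatch training loop. Epoch loss is the mean of the batch losses.
mlp_train <- function(params, X, Y, epochs, batch_size, lr,
                      adam_state = NULL) {
  n <- nrow(X)
  if (is.null(adam_state)) adam_state <- adam_init(params)
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    batch_losses <- numeric(length(starts))
    for (j in seq_along(starts)) {
      idx <- ord[starts[j]:min(starts[j] + batch_size - 1L, n)]
      g <- mlp_grad(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      batch_losses[j] <- g$loss
      upd <- adam_update(params, g, adam_state, lr)
      params <- upd$params
      adam_state <- upd$state
    }
    loss_history[e] <- mean(batch_losses)
  }
  list(params = params, loss_history = loss_history, adam_state = adam_state)
}
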