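# Minimal feed-forward network: fully connected layers, ReLU hidden
# activations, linear output, inverted dropout, Adam updates. All state is
# plain matrices so fitted models serialise as text. Gradients for each
# survival objective are supplied by the caller as dLoss/dOutput; this file
# only knows forward/backward through the stack.

mlp_init <- function(n_in, n_out, n_layers, n_nodes, seed) {
  with_seed(seed, {
    dims <- c(n_in, rep(n_nodes, n_layers), n_out)
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1L)) {
      # He initialisation for rectified units
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], 0,
                             sqrt(2 / dims[l])), dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    list(W = W, b = b, dims = dims)
  })
}

# X: n x n_in. Returns list(out, cache). Dropout applied to hidden
# activations only, scaled at train time (inverted dropout).
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- list(X)
  masks <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    if (l < L) {
      H <- pmax(Z, 0)
      if (training && dropout > 0) {
        m <- matrix(rbinom(length(H), 1L, 1 - dropout) / (1 - dropout),
                    nrow(H), ncol(H))
        H <- H * m
        masks[[l]] <- m
      }
    } else {
      H <- Z
    }
    A[[l + 1L]] <- H
  }
  list(out = H, A = A, masks = masks)
}

# dOut: n x n_out gradient of the loss wrt the network output.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      act <- cache$A[[l]]  # post-activation (and post-dropout) values
      if (!is.null(cache$masks[[l - 1L]])) {
        delta <- delta * cache$masks[[l - 1L]]
      }
      delta <- delta * (act > 0)
    }
  }
  list(dW = dW, db = db)
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
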