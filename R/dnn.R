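# Feed-forward neural network: fully connected ReLU hidden layers, 2-unit
# softmax output trained with categorical cross-entropy, inverted dropout,
# L2 weight decay and the Adagrad update rule.  Small, dependency-free and
# deterministic under the caller's RNG state, which is what the balanced-set
# sizes of the PU scheme need.

mlp_fit <- function(X, y, hidden = c(32, 32), dropout = 0.3, l2 = 0.01,
                    epochs = 50, batch_size = 128, lr = 0.01, eps = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, hidden, 2L)
  nl <- length(sizes) - 1L
  W <- G_W <- vector("list", nl)
  b <- G_b <- vector("list", nl)
  for (l in seq_len(nl)) {
    # Glorot uniform initialisation
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
    G_W[[l]] <- W[[l]] * 0
    G_b[[l]] <- b[[l]] * 0
  }
  Y <- cbind(1 - y, y)  # one-hot over {negative, positive}
  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      A <- X[idx, , drop = FALSE]
      acts <- list(A)
      masks <- vector("list", nl - 1L)
      for (l in seq_len(nl - 1L)) {
        Z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        H <- pmax(Z, 0)
        if (dropout > 0) {
          m <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
          H <- H * m / (1 - dropout)
          masks[[l]] <- m
        }
        acts[[l + 1L]] <- H
      }
      Z <- sweep(acts[[nl]] %*% W[[nl]], 2, b[[nl]], "+")
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z) / rowSums(exp(Z))
      delta <- (P - Y[idx, , drop = FALSE]) / length(idx)
      for (l in rev(seq_len(nl))) {
        gW <- crossprod(acts[[l]], delta) + l2 * W[[l]]
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(W[[l]])
          delta <- delta * (acts[[l]] > 0)
          if (dropout > 0) delta <- delta * masks[[l - 1L]] / (1 - dropout)
        }
        G_W[[l]] <- G_W[[l]] + gW^2
        G_b[[l]] <- G_b[[l]] + gb^2
        W[[l]] <- W[[l]] - lr * gW / sqrt(G_W[[l]] + eps)
        b[[l]] <- b[[l]] - lr * gb / sqrt(G_b[[l]] + eps)
      }
    }
  }
  structure(list(W = W, b = b, sizes = sizes), class = "mlp")
}

mlp_predict <- function(model, X) {
  nl <- length(model$W)
  A <- X
  for (l in seq_len(nl - 1L)) {
    A <- pmax(sweep(A %*% model$W[[l]], 2, model$b[[l]], "+"), 0)
  }
  Z <- sweep(A %*% model$W[[nl]], 2, model$b[[nl]], "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  unname(P[, 2])  # positive class = second softmax unit
}
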