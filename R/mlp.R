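## Minimal multilayer perceptron for multi-label probability estimation:
## ReLU hidden layers, one sigmoid output head per label, minibatch Adam on
## per-label weighted binary cross-entropy. Written in matrix form so all
## heavy lifting stays in BLAS.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else sigmoid(Z)
  }
  A
}

## Weighted BCE, clipped for numerical safety.
mlp_loss <- function(P, Y, Wgt) {
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  -mean(rowSums(Wgt * (Y * log(P) + (1 - Y) * log(1 - P))))
}

mlp_fit <- function(X, Y, sample_weights = NULL,
                    hidden = c(128L, 128L), learning_rate = 1e-3,
                    tol = 1e-4, patience = 10L, max_epochs = 300L,
                    batch_size = 200L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(sample_weights)) sample_weights <- matrix(1, n, ncol(Y))
  with_seed(seed, {
    sizes <- c(ncol(X), hidden, ncol(Y))
    par <- mlp_init(sizes)
    nl <- length(par$W)
    m <- lapply(par$W, function(w) w * 0); v <- m
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    best <- Inf; stall <- 0L
    batch_size <- min(batch_size, n)
    loss_trace <- numeric(0)

    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        A <- mlp_forward(par, X[idx, , drop = FALSE])
        nb <- length(idx)
        delta <- (A[[nl + 1L]] - Y[idx, , drop = FALSE]) *
          sample_weights[idx, , drop = FALSE] / nb
        t_step <- t_step + 1L
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
          }
          m[[l]] <- beta1 * m[[l]] + (1 - beta1) * gW
          v[[l]] <- beta2 * v[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mh <- m[[l]] / (1 - beta1^t_step)
          vh <- v[[l]] / (1 - beta2^t_step)
          par$W[[l]] <- par$W[[l]] - learning_rate * mh / (sqrt(vh) + eps)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          par$b[[l]] <- par$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      P <- mlp_forward(par, X)[[nl + 1L]]
      loss <- mlp_loss(P, Y, sample_weights)
      loss_trace <- c(loss_trace, loss)
      if (best - loss < tol) stall <- stall + 1L else stall <- 0L
      if (loss < best) best <- loss
      if (stall >= patience) break
    }
    list(par = par, loss_trace = loss_trace, n_epochs = length(loss_trace))
  })
}

mlp_predict <- function(fit, X) {
  A <- mlp_forward(fit$par, as.matrix(X))
  A[[length(A)]]
}
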