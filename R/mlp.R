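# Minimal fully connected regression network: ReLU hidden layers, linear
# scalar output, mean-squared-error loss, Adam updates. Implemented with
# plain matrix algebra; everything is deterministic given the seed.

mlp_init <- function(sizes, seed) {
  withr_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      # He-style scaling keeps ReLU activations well-conditioned
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                             sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(sizes = sizes, W = W, b = b)
  })
}

mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  A <- X
  acts <- if (keep) vector("list", L + 1L)
  if (keep) acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else Z
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = drop(A), acts = acts) else drop(A)
}

mlp_grad <- function(net, acts, y) {
  L <- length(net$W)
  B <- length(y)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- matrix(2 * (drop(acts[[L + 1L]]) - y) / B, ncol = 1L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
  }
  list(dW = dW, db = db)
}

mlp_train <- function(net, X, y, epochs, batch_size, learn_rate,
                      X_val = NULL, y_val = NULL) {
  L <- length(net$W)
  zero_like <- function(p) lapply(p, function(x) x * 0)
  mW <- zero_like(net$W); vW <- zero_like(net$W)
  mb <- zero_like(net$b); vb <- zero_like(net$b)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      fw <- mlp_forward(net, X[idx, , drop = FALSE], keep = TRUE)
      g <- mlp_grad(net, fw$acts, y[idx])
      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$dW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$dW[[l]]^2
        net$W[[l]] <- net$W[[l]] -
          learn_rate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$db[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$db[[l]]^2
        net$b[[l]] <- net$b[[l]] -
          learn_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
      }
    }
    loss <- mean((mlp_forward(net, X) - y)^2)
    if (!is.finite(loss))
      stop_hw("training diverged: non-finite loss at epoch ", ep,
              "; lower learn_rate or check the corpus",
              class = "hw_training_error")
    history[ep] <- loss
  }
  val_loss <- if (!is.null(X_val) && nrow(X_val) > 0)
    mean((mlp_forward(net, X_val) - y_val)^2) else NA_real_
  list(net = net, train_loss = history[epochs], val_loss = val_loss,
       history = history)
}
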