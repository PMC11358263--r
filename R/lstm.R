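## Recurrent sequence model: a single LSTM layer over the daily feature
## block, whose final hidden state is concatenated with the static covariates
## and passed through one ReLU dense layer to a linear scalar output.
## Implemented directly with vectorised matrix operations (batched forward
## pass, backpropagation through time, Adam); the windows here have only a
## handful of time steps, so this stays fast on one CPU and keeps the fitted
## model a plain, serialisable list of matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(n_feat, n_static, hidden, dense, seed) {
  set.seed(seed)
  glorot <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias at 1: remember by default
  list(Wx = glorot(n_feat, 4 * hidden), Wh = glorot(hidden, 4 * hidden), b = b,
       W1 = glorot(hidden + n_static, dense), b1 = rep(0, dense),
       W2 = glorot(dense, 1), b2 = 0,
       hidden = hidden, dense = dense)
}

## forward pass; returns prediction and (optionally) the cache for backprop
lstm_forward <- function(par, Xt, S, cache = FALSE) {
  H <- par$hidden
  N <- nrow(Xt[[1]])
  Tn <- length(Xt)
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  gates <- if (cache) vector("list", Tn) else NULL
  cs <- if (cache) vector("list", Tn + 1L) else NULL
  hs <- if (cache) vector("list", Tn + 1L) else NULL
  if (cache) { cs[[1]] <- cc; hs[[1]] <- h }
  bmat <- matrix(par$b, N, 4 * H, byrow = TRUE)
  for (t in seq_len(Tn)) {
    Z <- Xt[[t]] %*% par$Wx + h %*% par$Wh + bmat
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, H + 1:H, drop = FALSE])
    g <- tanh(Z[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(Z[, 3 * H + 1:H, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    if (cache) {
      gates[[t]] <- list(i = i, f = f, g = g, o = o)
      cs[[t + 1L]] <- cc
      hs[[t + 1L]] <- h
    }
  }
  Zhead <- cbind(h, S)
  A1 <- sweep(Zhead %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(A1, 0)
  yhat <- as.vector(H1 %*% par$W2 + par$b2)
  if (!cache) return(yhat)
  list(yhat = yhat, Zhead = Zhead, A1 = A1, H1 = H1,
       gates = gates, cs = cs, hs = hs)
}

## gradients of mean squared error wrt all parameters
lstm_backward <- function(par, Xt, S, y, fw) {
  H <- par$hidden
  N <- nrow(Xt[[1]])
  Tn <- length(Xt)
  dy <- matrix(2 * (fw$yhat - y) / N, ncol = 1)

  dW2 <- t(fw$H1) %*% dy
  db2 <- sum(dy)
  dH1 <- dy %*% t(par$W2)
  dA1 <- dH1 * (fw$A1 > 0)
  dW1 <- t(fw$Zhead) %*% dA1
  db1 <- colSums(dA1)
  dZhead <- dA1 %*% t(par$W1)
  dh <- dZhead[, 1:H, drop = FALSE]

  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(Tn))) {
    gt <- fw$gates[[t]]
    c_t <- fw$cs[[t + 1L]]
    c_prev <- fw$cs[[t]]
    tc <- tanh(c_t)
    do_ <- dh * tc
    dct <- dh * gt$o * (1 - tc^2) + dc_next
    di <- dct * gt$g
    df <- dct * c_prev
    dg <- dct * gt$i
    dc_next <- dct * gt$f
    dZ <- cbind(di * gt$i * (1 - gt$i),
                df * gt$f * (1 - gt$f),
                dg * (1 - gt$g^2),
                do_ * gt$o * (1 - gt$o))
    dWx <- dWx + t(Xt[[t]]) %*% dZ
    dWh <- dWh + t(fw$hs[[t]]) %*% dZ
    db <- db + colSums(dZ)
    dh <- dZ %*% t(par$Wh)
  }
  list(Wx = dWx, Wh = dWh, b = db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

lstm_loss <- function(par, Xt, S, y) mean((lstm_forward(par, Xt, S) - y)^2)

## Adam full-batch trainer with early stopping on an internal validation split
lstm_fit <- function(Xt, S, y, hidden = 16L, dense = 32L,
                     epochs = 200L, lr = 0.02, patience = 20L,
                     val_fraction = 0.1, seed = 1) {
  N <- length(y)
  n_feat <- ncol(Xt[[1]])
  par <- lstm_init(n_feat, ncol(S), hidden, dense, seed = seed)
  par$b2 <- mean(y)
  if (epochs < 1L) return(par)

  set.seed(seed + 1L)
  n_val <- if (val_fraction > 0 && N >= 10L) max(1L, floor(val_fraction * N)) else 0L
  idx_val <- if (n_val > 0L) sample.int(N, n_val) else integer(0)
  idx_tr <- setdiff(seq_len(N), idx_val)
  sel <- function(idx) list(Xt = lapply(Xt, function(M) M[idx, , drop = FALSE]),
                            S = S[idx, , drop = FALSE], y = y[idx])
  tr <- sel(idx_tr)
  va <- if (n_val > 0L) sel(idx_val) else NULL

  wnames <- c("Wx", "Wh", "b", "W1", "b1", "W2", "b2")
  mom <- lapply(par[wnames], function(w) w * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- par
  best_val <- Inf
  wait <- 0L
  step <- 0L
  for (ep in seq_len(epochs)) {
    fw <- lstm_forward(par, tr$Xt, tr$S, cache = TRUE)
    loss <- mean((fw$yhat - tr$y)^2)
    abort_if(!is.finite(loss),
             sprintf("non-finite training loss at epoch %d", ep))
    gr <- lstm_backward(par, tr$Xt, tr$S, tr$y, fw)
    step <- step + 1L
    for (w in wnames) {
      mom[[w]] <- beta1 * mom[[w]] + (1 - beta1) * gr[[w]]
      vel[[w]] <- beta2 * vel[[w]] + (1 - beta2) * gr[[w]]^2
      mhat <- mom[[w]] / (1 - beta1^step)
      vhat <- vel[[w]] / (1 - beta2^step)
      par[[w]] <- par[[w]] - lr * mhat / (sqrt(vhat) + eps)
    }
    monitor <- if (!is.null(va)) lstm_loss(par, va$Xt, va$S, va$y) else loss
    if (monitor < best_val - 1e-10) {
      best_val <- monitor
      best <- par
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best
}
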