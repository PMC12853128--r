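# Neural-network layer primitives with explicit forward/backward passes.
#
# Convolutional activations are stored as (B*T) x C matrices in t-major row
# order (all batch rows for position 1, then position 2, ...), which turns
# kernel-3 / pad-1 / stride-1 conv1d into a single matrix product against a
# column-shifted copy of the input (im2col).

# shift the time axis of a t-major (B*T) x C activation matrix
shift_time <- function(X, B, T, by) {
  Z <- matrix(0, nrow(X), ncol(X))
  if (by == 1) {          # row t holds input t-1
    if (T > 1) Z[(B + 1):(B * T), ] <- X[1:(B * (T - 1)), ]
  } else if (by == -1) {  # row t holds input t+1
    if (T > 1) Z[1:(B * (T - 1)), ] <- X[(B + 1):(B * T), ]
  } else Z <- X
  Z
}

conv1d_forward <- function(X, W, b, B, T) {
  Xcol <- cbind(shift_time(X, B, T, 1), X, shift_time(X, B, T, -1))
  Y <- Xcol %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = Y, Xcol = Xcol)
}

conv1d_backward <- function(dY, cache, W, B, T, C_in) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  d1 <- dXcol[, 1:C_in, drop = FALSE]
  d2 <- dXcol[, (C_in + 1):(2 * C_in), drop = FALSE]
  d3 <- dXcol[, (2 * C_in + 1):(3 * C_in), drop = FALSE]
  dX <- d2 + shift_time(d1, B, T, -1) + shift_time(d3, B, T, 1)
  list(dX = dX, dW = dW, db = db)
}

# Batch normalisation over rows (samples) for each column (feature/channel).
bn_forward <- function(X, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    rmean <- (1 - momentum) * rmean + momentum * mu
    n <- nrow(X)
    rvar <- (1 - momentum) * rvar + momentum * v * n / max(1, n - 1)
  } else {
    mu <- rmean
    xc <- sweep(X, 2, mu)
    v <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = Y, xhat = xhat, istd = istd, rmean = rmean, rvar = rvar)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  # dX = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, "*")
  dX <- sweep(dX, 2, cache$istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * mask, mask = mask)
}

maxpool2_forward <- function(X, B, T) {
  Tp <- T %/% 2
  i1 <- rep((seq_len(Tp) * 2 - 2) * B, each = B) + seq_len(B)
  i2 <- i1 + B
  X1 <- X[i1, , drop = FALSE]
  X2 <- X[i2, , drop = FALSE]
  take1 <- X1 >= X2
  list(out = X1 * take1 + X2 * !take1, take1 = take1, i1 = i1, i2 = i2,
       n_in = nrow(X))
}

maxpool2_backward <- function(dY, cache, C) {
  dX <- matrix(0, cache$n_in, C)
  dX[cache$i1, ] <- dY * cache$take1
  dX[cache$i2, ] <- dX[cache$i2, ] + dY * !cache$take1
  dX
}

linear_forward <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2, b, "+")
  list(out = Y, X = X)
}

linear_backward <- function(dY, cache, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

embedding_forward <- function(windows, E, B, T) {
  # windows: B x T integer matrix in [0, nrow(E)-1]; t-major output
  idx <- as.integer(windows) + 1L            # column-major = t-major rows
  if (any(idx < 1 | idx > nrow(E))) abort("window index out of range for embedding table")
  list(out = E[idx, , drop = FALSE], idx = idx)
}

embedding_backward <- function(dY, cache, n_vocab) {
  dE <- matrix(0, n_vocab, ncol(dY))
  agg <- rowsum(dY, group = cache$idx)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

# ---- Adam optimiser over a flat named list of arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
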