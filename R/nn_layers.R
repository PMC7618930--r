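# Minimal 1D neural-network layers on arrays of shape (n, channels, width),
# each with an explicit backward pass. Everything is plain matrix algebra:
# convolutions are im2col + one matrix product, which at W = 8 and a few
# dozen channels is far below the crossover where compiled kernels would pay.

# --- im2col ------------------------------------------------------------

# Flatten (n, C, W) to a (n*W) x C matrix with row index i + (t-1)*n.
flatten_cw <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(1L, 3L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
}

# Inverse of flatten_cw.
unflatten_cw <- function(M, n, C, W) {
  aperm(array(M, dim = c(n, W, C)), c(1L, 3L, 2L))
}

# --- same-padded 1D convolution ---------------------------------------

# weights: array (C_out, C_in, k); bias: length C_out. Odd k, zero padding
# of (k-1)/2 on both sides, output width == input width.
conv1d_forward <- function(X, weights, bias) {
  d <- dim(X); n <- d[1L]; C <- d[2L]; W <- d[3L]
  k <- dim(weights)[3L]; Cout <- dim(weights)[1L]
  p <- (k - 1L) %/% 2L
  Xpad <- array(0, dim = c(n, C, W + 2L * p))
  Xpad[, , (p + 1L):(p + W)] <- X
  M <- matrix(0, nrow = n * W, ncol = C * k)
  for (dk in seq_len(k)) {
    M[, ((dk - 1L) * C + 1L):(dk * C)] <-
      flatten_cw(Xpad[, , dk:(dk + W - 1L), drop = FALSE])
  }
  # weight matrix (C*k) x Cout with rows ordered (c within dk)
  Wm <- matrix(aperm(weights, c(2L, 3L, 1L)), nrow = C * k, ncol = Cout)
  out_mat <- M %*% Wm
  out_mat <- sweep(out_mat, 2L, bias, "+")
  list(out = unflatten_cw(out_mat, n, Cout, W),
       cache = list(M = M, Wm = Wm, n = n, C = C, W = W, k = k, p = p))
}

conv1d_backward <- function(dOut, cache) {
  n <- cache$n; C <- cache$C; W <- cache$W; k <- cache$k; p <- cache$p
  Cout <- ncol(cache$Wm)
  dOut_mat <- flatten_cw(dOut)
  dWm <- crossprod(cache$M, dOut_mat)               # (C*k) x Cout
  db <- colSums(dOut_mat)
  dM <- tcrossprod(dOut_mat, cache$Wm)              # (n*W) x (C*k)
  dXpad <- array(0, dim = c(n, C, W + 2L * p))
  for (dk in seq_len(k)) {
    dXpad[, , dk:(dk + W - 1L)] <- dXpad[, , dk:(dk + W - 1L), drop = FALSE] +
      unflatten_cw(dM[, ((dk - 1L) * C + 1L):(dk * C), drop = FALSE], n, C, W)
  }
  dW <- aperm(array(dWm, dim = c(C, k, Cout)), c(3L, 1L, 2L))
  list(dX = dXpad[, , (p + 1L):(p + W), drop = FALSE], dW = dW, db = db)
}

# --- ReLU --------------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dOut, mask) dOut * mask

# --- max pooling, width 2, stride 2 -----------------------------------

maxpool2_forward <- function(X) {
  W <- dim(X)[3L]
  odd <- X[, , seq.int(1L, W, 2L), drop = FALSE]
  even <- X[, , seq.int(2L, W, 2L), drop = FALSE]
  take_odd <- odd >= even   # ties go to the earlier position
  list(out = pmax(odd, even), cache = list(take_odd = take_odd, W = W))
}

maxpool2_backward <- function(dOut, cache) {
  d <- dim(dOut)
  dX <- array(0, dim = c(d[1L], d[2L], cache$W))
  dX[, , seq.int(1L, cache$W, 2L)] <- dOut * cache$take_odd
  dX[, , seq.int(2L, cache$W, 2L)] <- dOut * !cache$take_odd
  dX
}

# --- transposed convolution, kernel 2, stride 2 (up-conv) -------------

# weights: array (C_out, C_in, 2); doubles the width.
tconv2_forward <- function(X, weights, bias) {
  d <- dim(X); n <- d[1L]; C <- d[2L]; W <- d[3L]
  Cout <- dim(weights)[1L]
  Xm <- flatten_cw(X)                                # (n*W) x C
  out <- array(0, dim = c(n, Cout, 2L * W))
  for (j in 1:2) {
    Oj <- Xm %*% t(matrix(weights[, , j], nrow = Cout, ncol = C))
    Oj <- sweep(Oj, 2L, bias, "+")
    out[, , seq.int(j, 2L * W, 2L)] <- unflatten_cw(Oj, n, Cout, W)
  }
  list(out = out, cache = list(Xm = Xm, n = n, C = C, W = W, Cout = Cout,
                               weights = weights))
}

tconv2_backward <- function(dOut, cache) {
  n <- cache$n; C <- cache$C; W <- cache$W; Cout <- cache$Cout
  dW <- array(0, dim = dim(cache$weights))
  db <- numeric(Cout)
  dXm <- matrix(0, nrow = n * W, ncol = C)
  for (j in 1:2) {
    dOj <- flatten_cw(dOut[, , seq.int(j, 2L * W, 2L), drop = FALSE])  # (n*W) x Cout
    Wj <- matrix(cache$weights[, , j], nrow = Cout, ncol = C)
    dW[, , j] <- crossprod(dOj, cache$Xm)            # Cout x C
    db <- db + colSums(dOj)
    dXm <- dXm + dOj %*% Wj
  }
  list(dX = unflatten_cw(dXm, n, C, W), dW = dW, db = db)
}

# --- Adam optimizer ----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
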