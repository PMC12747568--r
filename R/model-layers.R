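# Neural-network layer primitives. Sequence activations are stored as
# (T, N, d) arrays so that matrix(A, T*N, d) is a valid 2-D view for BLAS,
# and A[t, , ] is the batch slice at one timestep. All layers return both
# their output and the cache needed for the analytic backward pass; gradient
# correctness is pinned by finite-difference tests.

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-z))`, the output nonlinearity mapping a logit to an
#' intoxication probability.
#'
#' @param z numeric vector or array.
#' @return values in (0, 1), same shape as `z`.
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Binary cross-entropy loss
#'
#' `-(y log p + (1 - y) log(1 - p))` averaged over the batch, with `p`
#' clipped to `[eps, 1 - eps]`.
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities.
#' @param eps clipping constant (default 1e-7).
#' @return mean loss (scalar >= 0).
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

# --- initialization -------------------------------------------------------

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

# --- conv1d ('same' padding, ReLU) ----------------------------------------

conv1d_init <- function(c_in, c_out, k) {
  list(W = glorot(k * c_in, c_out, dims = c(k, c_in, c_out)),
       b = numeric(c_out))
}

conv1d_forward <- function(A, W, b) {
  dims <- dim(A); T <- dims[1]; N <- dims[2]; c_in <- dims[3]
  k <- dim(W)[1]; c_out <- dim(W)[3]
  pad_left <- (k - 1L) %/% 2L
  Ap <- array(0, c(T + k - 1L, N, c_in))
  Ap[(pad_left + 1L):(pad_left + T), , ] <- A
  Z <- matrix(rep(b, each = T * N), T * N, c_out)
  for (j in seq_len(k)) {
    Xj <- matrix(Ap[j:(j + T - 1L), , , drop = FALSE], T * N, c_in)
    Z <- Z + Xj %*% matrix(W[j, , ], c_in, c_out)
  }
  mask <- Z > 0
  out <- array(Z * mask, c(T, N, c_out))
  list(out = out, cache = list(Ap = Ap, mask = mask, W = W,
                               T = T, N = N, c_in = c_in, k = k,
                               pad_left = pad_left))
}

conv1d_backward <- function(dout, cache) {
  with(cache, {
    c_out <- dim(W)[3]
    dZ <- matrix(dout, T * N, c_out) * mask
    dW <- array(0, dim(W))
    dAp <- array(0, dim(Ap))
    for (j in seq_len(k)) {
      Xj <- matrix(Ap[j:(j + T - 1L), , , drop = FALSE], T * N, c_in)
      dW[j, , ] <- crossprod(Xj, dZ)
      dXj <- dZ %*% t(matrix(W[j, , ], c_in, c_out))
      dAp[j:(j + T - 1L), , ] <- dAp[j:(j + T - 1L), , , drop = FALSE] +
        array(dXj, c(T, N, c_in))
    }
    list(dA = dAp[(pad_left + 1L):(pad_left + T), , , drop = FALSE],
         dW = dW, db = colSums(dZ))
  })
}

# --- bidirectional LSTM ---------------------------------------------------

lstm_init <- function(c_in, H) {
  Wx <- glorot(c_in, 4 * H, dims = c(c_in, 4 * H))
  Wh <- glorot(H, 4 * H, dims = c(H, 4 * H))
  b <- numeric(4 * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias init
  list(Wx = Wx, Wh = Wh, b = b)
}

# A: (T, N, c_in) -> (T, N, H); reverse=TRUE runs the sequence backwards.
lstm_dir_forward <- function(A, p, reverse = FALSE) {
  T <- dim(A)[1]
  Xc <- aperm(A, c(2, 3, 1))                     # (N, c_in, T) cube
  if (reverse) Xc <- Xc[, , T:1, drop = FALSE]
  fw <- lstm_forward_cpp(Xc, p$Wx, p$Wh, p$b)
  H <- fw$H
  out <- aperm(if (reverse) H[, , T:1, drop = FALSE] else H, c(3, 1, 2))
  list(out = out, cache = list(fw = fw, Xc = Xc, p = p, reverse = reverse, T = T))
}

lstm_dir_backward <- function(dout, cache) {
  with(cache, {
    dHc <- aperm(dout, c(2, 3, 1))               # (N, H, T)
    if (reverse) dHc <- dHc[, , T:1, drop = FALSE]
    bw <- lstm_backward_cpp(Xc, p$Wx, p$Wh, fw$H, fw$C, fw$I, fw$F, fw$G,
                            fw$O, fw$TC, dHc)
    dXc <- bw$dX
    if (reverse) dXc <- dXc[, , T:1, drop = FALSE]
    list(dA = aperm(dXc, c(3, 1, 2)),
         dWx = bw$dWx, dWh = bw$dWh, db = as.numeric(bw$db))
  })
}

bilstm_forward <- function(A, pf, pb) {
  f <- lstm_dir_forward(A, pf, reverse = FALSE)
  b <- lstm_dir_forward(A, pb, reverse = TRUE)
  T <- dim(A)[1]; N <- dim(A)[2]; H <- dim(f$out)[3]
  out <- array(0, c(T, N, 2L * H))
  out[, , 1:H] <- f$out
  out[, , (H + 1L):(2L * H)] <- b$out
  list(out = out, cache = list(f = f$cache, b = b$cache, H = H))
}

bilstm_backward <- function(dout, cache) {
  H <- cache$H
  gf <- lstm_dir_backward(dout[, , 1:H, drop = FALSE], cache$f)
  gb <- lstm_dir_backward(dout[, , (H + 1L):(2L * H), drop = FALSE], cache$b)
  list(dA = gf$dA + gb$dA, f = gf, b = gb)
}

# --- global average pooling ----------------------------------------------

gap_forward <- function(A) {
  out <- colMeans(A, dims = 1)                   # (N, d)
  list(out = out, cache = dim(A))
}

gap_backward <- function(dout, cache) {
  T <- cache[1]
  array(rep(dout / T, each = T), cache)
}

# --- dense / dropout ------------------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), b = numeric(d_out))
}

dense_forward <- function(X, W, b, relu = TRUE) {
  Z <- sweep(X %*% W, 2, b, "+")
  mask <- if (relu) Z > 0 else NULL
  list(out = if (relu) Z * mask else Z,
       cache = list(X = X, W = W, mask = mask))
}

dense_backward <- function(dout, cache) {
  dZ <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dX = dZ %*% t(cache$W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

# Inverted dropout: scaling at train time, identity at inference.
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# row-wise softmax with max-shift stabilization
softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

# backward through row-softmax: dS = A * (dA - rowSums(dA * A))
softmax_rows_backward <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}
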