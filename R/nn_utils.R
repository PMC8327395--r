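# Small neural-network toolbox shared by the adversarial augmenter and the
# LSTM classifier. Everything is plain matrix algebra with manual
# backpropagation — the networks here are tiny (12-dimensional feature
# vectors), so BLAS-backed base R is entirely adequate.

sigmoid <- function(x) plogis(x)
leaky_relu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
d_leaky_relu <- function(x, a = 0.2) ifelse(x > 0, 1, a)
relu <- function(x) pmax(x, 0)
d_relu <- function(x) as.numeric(x > 0)

# orthogonal initialization via QR of a Gaussian matrix
orthogonal_init <- function(nrow, ncol) {
  a <- matrix(rnorm(max(nrow, ncol)^2), max(nrow, ncol))
  q <- qr.Q(qr(a))
  q[seq_len(nrow), seq_len(ncol), drop = FALSE]
}

gaussian_init <- function(nrow, ncol, sd = 0.02) {
  matrix(rnorm(nrow * ncol, 0, sd), nrow, ncol)
}

# Adam optimizer state & step (applied parameter-by-parameter)
adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, beta1, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# RMSProp optimizer (the classifier's optimizer)
rmsprop_state <- function(params) lapply(params, function(p) p * 0)

rmsprop_step <- function(params, grads, state, lr, decay = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]] <- decay * state[[nm]] + (1 - decay) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# --- 1-D "same" convolution on length-L sequences -------------------------
# Sequences are stored as arrays [batch, L, channels]. The kernel has length
# 5 and the convolution is linear, so forward and backward passes reduce to
# five shifted outer/matrix products.

shift_slab <- function(a, offset, L) {
  # returns a[, t + offset, ] with zero padding, same shape as a
  out <- a * 0
  src <- seq_len(L) + offset
  ok <- src >= 1 & src <= L
  if (any(ok)) out[, which(ok), ] <- a[, src[ok], , drop = FALSE]
  out
}

conv1d_forward <- function(x, K, b) {
  # x: [B, L, Cin]; K: [k, Cin, Cout]; b: [Cout] -> out [B, L, Cout]
  B <- dim(x)[1]; L <- dim(x)[2]
  k <- dim(K)[1]; cin <- dim(K)[2]; cout <- dim(K)[3]
  half <- (k - 1) %/% 2
  out <- array(0, c(B, L, cout))
  out_m <- matrix(0, B * L, cout)
  for (j in seq_len(k)) {
    xs <- shift_slab(x, j - 1 - half, L)
    xm <- matrix(xs, B * L, cin)
    out_m <- out_m + xm %*% matrix(K[j, , ], cin, cout)
  }
  out_m <- sweep(out_m, 2, b, "+")
  array(out_m, c(B, L, cout))
}

conv1d_backward <- function(x, K, dout) {
  # gradients of loss wrt kernel, bias and input
  B <- dim(x)[1]; L <- dim(x)[2]
  k <- dim(K)[1]; cin <- dim(K)[2]; cout <- dim(K)[3]
  half <- (k - 1) %/% 2
  dout_m <- matrix(dout, B * L, cout)
  dK <- array(0, dim(K))
  dx <- array(0, dim(x))
  for (j in seq_len(k)) {
    xs <- shift_slab(x, j - 1 - half, L)
    xm <- matrix(xs, B * L, cin)
    dK[j, , ] <- crossprod(xm, dout_m)
    contrib <- array(dout_m %*% t(matrix(K[j, , ], cin, cout)), c(B, L, cin))
    dx <- dx + shift_slab(contrib, -(j - 1 - half), L)
  }
  db <- colSums(dout_m)
  list(dK = dK, db = db, dx = dx)
}

# compiled code hands bias row-vectors back as 1 x n matrices; flatten those
# (column matrices like the discriminator's final weight stay matrices)
drop_dims <- function(x) {
  if (is.matrix(x) && nrow(x) == 1 && ncol(x) > 1) return(as.numeric(x))
  if (is.matrix(x) && nrow(x) == 1 && ncol(x) == 1) return(as.numeric(x))
  x
}
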