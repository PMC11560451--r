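# Dense linear-algebra building blocks for the network: batch normalization,
# zero-padded 3x3 convolution via index-gather im2col + BLAS matmul, softmax,
# and the Adam optimizer with decoupled weight decay. All backward passes are
# written analytically; there is no autodiff tape.

relu <- function(x) relu_cpp(x)
drelu <- function(d, y) drelu_cpp(d, y)      # d masked where y <= 0
sigmoid <- function(x) 1 / (1 + exp(-x))

# Sum an (ch, L, bt) array over its position dimension -> (ch, bt) matrix.
sum_positions <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L])
  out <- rowsum(x, group = rep.int(seq_len(d[1L]), d[2L]))
  dim(out) <- c(d[1L], d[3L])
  out
}

# Broadcast a (ch, bt) matrix over L positions -> (ch, L, bt) array.
broadcast_positions <- function(m, L) {
  out <- m[, rep(seq_len(ncol(m)), each = L), drop = FALSE]
  dim(out) <- c(nrow(m), L, ncol(m))
  out
}

# ---- batch normalization (input: obs x channels matrix) ---------------------

bn_forward <- function(x, g, b, rm, rv, train, eps = 1e-5, momentum = 0.1) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v <- pmax(v, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - rep(mu, each = nrow(x))) * rep(inv, each = nrow(x))
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g, train = train),
       rm = rm, rv = rv)
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  if (cache$train) {
    m1 <- colMeans(dy)
    m2 <- colMeans(dy * xhat)
    dx <- rep(cache$g * cache$inv, each = n) *
      (dy - rep(m1, each = n) - xhat * rep(m2, each = n))
  } else {
    dx <- dy * rep(cache$g * cache$inv, each = n)
  }
  list(dx = dx, dg = dg, db = db)
}

# ---- 3x3 same-padding convolution -------------------------------------------

# Compiled per-tap GEMM implementation (src/conv3x3.cpp). Activations are
# (cin, h*w, batch) arrays with the image row fastest in the position index.
conv3x3_forward <- function(X, W, b, h, w) {
  Y <- conv3x3_fwd_cpp(X, W, b, h, w)
  list(y = Y, X = X, h = h, w = w)
}

conv3x3_backward <- function(dY, W, cache) {
  conv3x3_bwd_cpp(dY, cache$X, W, cache$h, cache$w)
}

# ---- softmax over positions (dim 2 of an (heads, L, batch) array) -----------

softmax_positions <- function(Q) {
  d <- dim(Q)
  mx <- apply(Q, c(1L, 3L), max)
  dim(mx) <- c(d[1L], d[3L])
  E <- exp(Q - broadcast_positions(mx, d[2L]))
  E / broadcast_positions(sum_positions(E), d[2L])
}

softmax_positions_backward <- function(dS, S) {
  S * (dS - broadcast_positions(sum_positions(dS * S), dim(S)[2L]))
}

# ---- Adam with decoupled weight decay ---------------------------------------

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  opt$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  params <- param_map(function(p, m, v) {
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
  }, params, opt$m, opt$v)
  list(params = params, opt = opt)
}
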