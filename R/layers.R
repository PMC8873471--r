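# Differentiable layer primitives used by the V-net experts and the gating
# network. Each *_fw returns the output plus whatever the matching *_bw
# needs; backward passes are hand-written (no autograd dependency). Tensors
# are base-R arrays, spatial dims first, channel dim last.

relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, mask = x > 0)
}

relu_bw <- function(cache, gy) {
  gy * cache$mask
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Instance normalization over all spatial positions of each channel, with
# learnable per-channel affine terms (gamma, beta). Works for (X,Y,C) and
# (X,Y,Z,C) tensors alike: the last dim is the channel dim.
instnorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  nc <- d[length(d)]
  sp <- prod(d[-length(d)])
  xm <- matrix(x, sp, nc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, gamma = gamma, dims = d)
}

instnorm_bw <- function(cache, gy) {
  d <- cache$dims
  nc <- d[length(d)]
  sp <- prod(d[-length(d)])
  gym <- matrix(gy, sp, nc)
  gbeta <- colSums(gym)
  ggamma <- colSums(gym * cache$xhat)
  gxhat <- sweep(gym, 2L, cache$gamma, `*`)
  # d/dx of (x - mu) * inv with mu, var functions of x
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- sweep(gxhat, 2L, m1) - sweep(cache$xhat, 2L, m2, `*`)
  gx <- sweep(gx, 2L, cache$inv, `*`)
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Nearest-neighbour upsampling of a (X,Y,Z,C) tensor to a target spatial
# size; inverse of ceil-mode 2x pooling: target index t reads source
# ceiling(t/2).
upsample3d_fw <- function(x, target) {
  d <- dim(x)
  ix <- ceiling(seq_len(target[1]) / 2)
  iy <- ceiling(seq_len(target[2]) / 2)
  iz <- ceiling(seq_len(target[3]) / 2)
  stopifnot(max(ix) <= d[1], max(iy) <= d[2], max(iz) <= d[3])
  y <- x[ix, iy, iz, , drop = FALSE]
  list(y = y, src_dims = d, target = target)
}

upsample3d_bw <- function(cache, gy) {
  d <- cache$src_dims
  t <- cache$target
  gx <- array(0, dim = d)
  for (ox in 0:1) {
    sx <- seq.int(1L + ox, t[1], by = 2L)
    if (!length(sx)) next
    for (oy in 0:1) {
      sy <- seq.int(1L + oy, t[2], by = 2L)
      if (!length(sy)) next
      for (oz in 0:1) {
        sz <- seq.int(1L + oz, t[3], by = 2L)
        if (!length(sz)) next
        gx[ceiling(sx / 2), ceiling(sy / 2), ceiling(sz / 2), ] <-
          gx[ceiling(sx / 2), ceiling(sy / 2), ceiling(sz / 2), , drop = FALSE] +
          gy[sx, sy, sz, , drop = FALSE]
      }
    }
  }
  gx
}

dense_fw <- function(x, W, b) {
  list(y = as.vector(W %*% x + b), x = x)
}

dense_bw <- function(cache, W, gy) {
  list(gx = as.vector(crossprod(W, gy)),
       gW = outer(gy, cache$x),
       gb = gy)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Jacobian-vector product of softmax: g_z = diag(a) g - a (a . g)
softmax_bw <- function(alpha, galpha) {
  alpha * galpha - alpha * sum(alpha * galpha)
}
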