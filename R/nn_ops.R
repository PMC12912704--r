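# Low-level differentiable primitives used by the condition encoder and the
# denoiser. Every forward returns what its matching backward needs; backward
# functions return gradients w.r.t. inputs and parameters. All of this is
# plain dense base-R linear algebra: the matrices involved are small
# (hundreds of rows/columns) and the call overhead, not flops, dominates.

rowBroadcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

linFwd <- function(x, W, b) x %*% W + rowBroadcast(b, nrow(x))

linBwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

geluFwd <- function(x) x * stats::pnorm(x)

geluBwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

# Layer normalization across the feature axis of each row.
lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = xhat * rowBroadcast(g, nrow(x)) + rowBroadcast(b, nrow(x)),
       xhat = xhat, inv = inv)
}

lnBwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  dxhat <- dy * rowBroadcast(g, nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# Cross-covariance attention: the map lives on the feature (gene) axis.
# Q,K,V are (cells x d); A = softmax over columns of K'Q/sqrt(dk) is (d x d);
# every column of A sums to one; output is V A (cells x d).
xcaFwd <- function(Q, K, V, dk) {
  S <- crossprod(K, Q) / sqrt(dk)
  S <- sweep(S, 2, apply(S, 2, max), "-")
  E <- exp(S)
  A <- sweep(E, 2, colSums(E), "/")
  list(O = V %*% A, A = A)
}

xcaBwd <- function(Q, K, V, dk, cache, dO) {
  A <- cache$A
  dV <- dO %*% t(A)
  dA <- crossprod(V, dO)
  dS <- A * (dA - rowBroadcast(colSums(dA * A), nrow(A)))
  dS <- dS / sqrt(dk)
  list(dQ = K %*% dS, dK = Q %*% t(dS), dV = dV)
}

# Standard token-axis (cell-axis) self-attention, used by the ablation that
# swaps XCA out. A = softmax over rows of Q K'/sqrt(dk) is (cells x cells).
selfAttFwd <- function(Q, K, V, dk) {
  S <- Q %*% t(K) / sqrt(dk)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  A <- E / rowSums(E)
  list(O = A %*% V, A = A)
}

selfAttBwd <- function(Q, K, V, dk, cache, dO) {
  A <- cache$A
  dV <- crossprod(A, dO)
  dA <- dO %*% t(V)
  dS <- A * (dA - rowSums(dA * A))
  dS <- dS / sqrt(dk)
  list(dQ = dS %*% K, dK = crossprod(dS, Q), dV = dV)
}

# Depthwise 1-D convolution along the feature axis, window 3, edge-replicate
# padding (replication keeps constant rows constant under a normalized
# kernel). kern is (3 x d): kern[1,] weights the left neighbour, kern[2,] the
# centre, kern[3,] the right neighbour of each feature column.
dwConvFwd <- function(x, kern, b) {
  n <- nrow(x); d <- ncol(x)
  xl <- cbind(x[, 1], x[, -d, drop = FALSE])
  xr <- cbind(x[, -1, drop = FALSE], x[, d])
  xl * rowBroadcast(kern[1, ], n) + x * rowBroadcast(kern[2, ], n) +
    xr * rowBroadcast(kern[3, ], n) + rowBroadcast(b, n)
}

dwConvBwd <- function(x, kern, dz) {
  n <- nrow(x); d <- ncol(x)
  xl <- cbind(x[, 1], x[, -d, drop = FALSE])
  xr <- cbind(x[, -1, drop = FALSE], x[, d])
  t1 <- dz * rowBroadcast(kern[1, ], n)
  t2 <- dz * rowBroadcast(kern[2, ], n)
  t3 <- dz * rowBroadcast(kern[3, ], n)
  dx <- t2
  dx[, -d] <- dx[, -d, drop = FALSE] + t1[, -1, drop = FALSE]
  dx[, 1] <- dx[, 1] + t1[, 1]
  dx[, -1] <- dx[, -1, drop = FALSE] + t3[, -d, drop = FALSE]
  dx[, d] <- dx[, d] + t3[, d]
  list(dx = dx,
       dk = rbind(colSums(dz * xl), colSums(dz * x), colSums(dz * xr)),
       db = colSums(dz))
}

# Sinusoidal position encoding of an integer timestep at a given even width.
sinusoidalEmbedding <- function(t, width, base = 1e4) {
  if (width %% 2 != 0) stop("embedding width must be even")
  half <- width / 2
  freqs <- base^(-(seq_len(half) - 1) / half)
  c(sin(t * freqs), cos(t * freqs))
}

# Xavier/Glorot-scaled random matrix.
xavier <- function(nin, nout, gain = 1) {
  matrix(stats::rnorm(nin * nout, 0, gain * sqrt(2 / (nin + nout))), nin, nout)
}
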