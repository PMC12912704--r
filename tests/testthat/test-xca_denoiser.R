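test_that("time embedding is deterministic and distinguishes timesteps", {
  v1 <- embedTime(1, 64, Tmax = 1000)
  expect_identical(v1, embedTime(1, 64, Tmax = 1000))
  vT <- embedTime(1000, 64, Tmax = 1000)
  cosSim <- sum(v1 * vT) / sqrt(sum(v1^2) * sum(vT^2))
  expect_lt(cosSim, 0.99)
  expect_error(embedTime(0, 64, Tmax = 1000), "out of range")
  expect_error(embedTime(5, 63), "even")
})

test_that("xcAttention matches hand computation on a 2-cell/2-gene instance", {
  Q <- matrix(c(1, 2, 3, 4), 2, 2)
  K <- matrix(c(0.5, -1, 2, 0), 2, 2)
  V <- matrix(c(1, 0, 0, 1), 2, 2)
  dk <- 2
  S <- t(K) %*% Q / sqrt(dk)
  A <- apply(S, 2, function(col) exp(col) / sum(exp(col)))
  want <- V %*% A
  got <- xcAttention(Q, K, V, dk)
  expect_equal(unclass(got), want, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(got, "attentionMap"), A, tolerance = 1e-6)
})

test_that("the attention map is column-stochastic of shape g x g", {
  withr::with_seed(1, {
    Q <- matrix(rnorm(40), 8, 5)
    K <- matrix(rnorm(40), 8, 5)
    V <- matrix(rnorm(40), 8, 5)
  })
  got <- xcAttention(Q, K, V, 5)
  A <- attr(got, "attentionMap")
  expect_identical(dim(A), c(5L, 5L))
  expect_equal(colSums(A), rep(1, 5), tolerance = 1e-12)
  expect_error(xcAttention(Q, K, V, 0), "dk")
  expect_error(xcAttention(Q, K[1:3, ], V), "cell dimension")
})

test_that("saturated one-hot keys/queries make the map the identity", {
  Q <- K <- 50 * diag(3)
  V <- matrix(rnorm(9), 3, 3)
  got <- xcAttention(Q, K, V, 1)
  expect_equal(attr(got, "attentionMap"), diag(3), tolerance = 1e-6)
  expect_equal(unclass(got), V, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("self-attention fallback is row-stochastic and matches scalars", {
  Q <- matrix(c(1, 0, 0.5, 2), 2, 2)
  K <- matrix(c(1, 1, -1, 0), 2, 2)
  V <- matrix(c(2, 1, 0, 3), 2, 2)
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  want <- A %*% V
  got <- selfAttentionFallback(Q, K, V, 2)
  expect_equal(unclass(got), want, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(rowSums(attr(got, "attentionMap")), c(1, 1), tolerance = 1e-12)
})

test_that("LPI: identity kernel is a no-op, normalized kernel keeps constants", {
  x <- matrix(rnorm(21), 3, 7)
  idk <- rbind(0, 1, 0)[, rep(1, 7)]
  expect_equal(lpiBlock(x, idk), x, tolerance = 1e-12)
  avg <- matrix(1 / 3, 3, 7)
  cst <- matrix(5, 2, 7)
  expect_equal(lpiBlock(cst, avg), cst, tolerance = 1e-12)
  expect_error(lpiBlock(matrix(1, 2, 2), rbind(0, 1, 0)[, c(1, 1)]), "window")
})

test_that("LPI window-3 mixing matches a brute-force sliding window", {
  x <- matrix(rnorm(7), 1, 7)
  withr::with_seed(2, {
    kern <- matrix(rnorm(21), 3, 7)
    bias <- rnorm(7)
  })
  got <- lpiBlock(x, kern, bias)
  xp <- c(x[1, 1], x[1, ], x[1, 7])  # edge-replicate padding
  want <- vapply(seq_len(7), function(d) {
    sum(xp[d + 0:2] * kern[, d]) + bias[d]
  }, numeric(1))
  expect_equal(as.vector(got), want, tolerance = 1e-12)
})

test_that("denoiser output matches input shape and is deterministic", {
  cfg <- microModelConfig(nGenes = 10L)
  model <- diffusionModel(10L, cfg, seed = 1)
  withr::with_seed(3, {
    x <- matrix(rnorm(60), 6, 10)
    cond <- matrix(rnorm(60), 6, 10)
  })
  out <- denoiserForward(model, x, cond, t = 5)
  expect_identical(dim(out), dim(x))
  expect_identical(out, denoiserForward(model, x, cond, t = 5))
  expect_error(denoiserForward(model, x[, 1:5], cond[, 1:5], 5), "mismatch")
})

test_that("single-block single-head forward equals manual composition", {
  ns <- asNamespace("diffuseST")
  cfg <- modelConfig(nGenes = 6L, width = 8L, nBlocks = 1L, nHeads = 1L,
                     T = 20L, ablation = "no_bilstm")
  p <- ns$initDenoiserParams(cfg, seed = 4)
  withr::with_seed(5, {
    x <- matrix(rnorm(24), 4, 6)
    cond <- matrix(rnorm(24), 4, 6)
  })
  t <- 7
  got <- ns$netForward(p, cfg, x, cond, t)$eps

  # straight-line re-composition from the exported / primitive pieces
  tv <- embedTime(t, 8, Tmax = 20, mlp = p$time)
  h <- x %*% p$inp$W + matrix(p$inp$b, 4, 8, byrow = TRUE)
  cnd <- cond %*% p$cond$W + matrix(p$cond$b + tv, 4, 8, byrow = TRUE)
  bp <- p$blocks[[1]]
  ln1 <- ns$lnFwd(h, bp$ln1$g, bp$ln1$b)$y
  att <- xcAttention(ln1 %*% bp$att$Wq, cnd %*% bp$att$Wk, cnd %*% bp$att$Wv,
                     dk = 8)
  h <- h + unclass(att) %*% bp$att$Wo + matrix(bp$att$bo, 4, 8, byrow = TRUE)
  ln2 <- ns$lnFwd(h, bp$ln2$g, bp$ln2$b)$y
  h <- h + lpiBlock(ln2, bp$lpi$K1, bp$lpi$b1, bp$lpi$K2, bp$lpi$b2)
  ln3 <- ns$lnFwd(h, bp$ln3$g, bp$ln3$b)$y
  h <- h + ns$geluFwd(ln3 %*% bp$ffn$W1 +
                        matrix(bp$ffn$b1, 4, 16, byrow = TRUE)) %*%
    bp$ffn$W2 + matrix(bp$ffn$b2, 4, 8, byrow = TRUE)
  lnF <- ns$lnFwd(h, p$out$ln$g, p$out$ln$b)$y
  want <- lnF %*% p$out$W + matrix(p$out$b, 4, 6, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("the denoiser is cell-permutation-equivariant without the recurrent path", {
  cfg <- microModelConfig(nGenes = 8L, ablation = "no_bilstm")
  model <- diffusionModel(8L, cfg, seed = 2)
  withr::with_seed(6, {
    x <- matrix(rnorm(40), 5, 8)
    cond <- matrix(rnorm(40), 5, 8)
  })
  out <- denoiserForward(model, x, cond, 3)
  perm <- c(3, 1, 5, 2, 4)
  outP <- denoiserForward(model, x[perm, ], cond[perm, ], 3)
  expect_equal(outP, out[perm, ], tolerance = 1e-10)
})

test_that("ablation flags rewire the model as documented", {
  expect_false(modelConfig(10, ablation = "no_bilstm")$useBilstm)
  expect_identical(modelConfig(10, ablation = "no_xca")$attention, "self")
  only1 <- modelConfig(10, ablation = "diffusion_bilstm_only")
  expect_identical(only1$attention, "self")
  expect_true(only1$useBilstm)
  expect_identical(only1$klWeight, 0)
  only2 <- modelConfig(10, ablation = "diffusion_xca_only")
  expect_false(only2$useBilstm)
  expect_identical(only2$attention, "xca")
  expect_identical(only2$klWeight, 0)
  # the dimensionality rules
  expect_identical(modelConfig(600)$width, 1024L)
  expect_identical(modelConfig(600)$batchSize, 512L)
  expect_identical(modelConfig(600)$klWeight, 0.02)
  expect_identical(modelConfig(100)$width, 512L)
  expect_identical(modelConfig(100)$batchSize, 2048L)
  expect_identical(modelConfig(100)$klWeight, 2.8)
})

test_that("one optimization step on a fixed tiny batch decreases the loss", {
  ns <- asNamespace("diffuseST")
  cfg <- microModelConfig(nGenes = 8L)
  p <- ns$initDenoiserParams(cfg, seed = 9)
  withr::with_seed(10, {
    x <- matrix(rnorm(48), 6, 8)
    cond <- matrix(rnorm(48), 6, 8)
    eps <- matrix(rnorm(48), 6, 8)
  })
  mB <- matrix(rep(c(1, 1, 1, 0, 0, 1, 0, 0), each = 6), 6, 8)
  lossAt <- function(pp) {
    trainingLoss(eps, ns$netForward(pp, cfg, x, cond, 3)$eps, mB, 1)$total
  }
  fwd <- ns$netForward(p, cfg, x, cond, 3, keepCache = TRUE)
  gr <- ns$netBackward(p, cfg, fwd$cache, ns$lossGrad(eps, fwd$eps, mB, 1))
  # plain gradient step with a small rate
  p2 <- ns$adamUpdate(p, gr, ns$adamInit(p), lr = 1e-3, weightDecay = 0)$params
  expect_lt(lossAt(p2), lossAt(p))
})
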