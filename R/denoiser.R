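# The noise-prediction network: an input embedding, a condition path
# (bidirectional LSTM encoder + linear projection, or the raw masked matrix
# when ablated), a timestep embedding broadcast-added to the condition, and a
# stack of pre-normalized transformer blocks. Each block applies
# cross-covariance attention (queries from the running signal, keys/values
# from the condition), a local patch interaction (LPI) block, and a
# feed-forward sublayer, all with residual connections.

#' Model hyperparameter configuration
#'
#' Defaults follow the published operating point: 6 attention blocks with 16
#' heads; hidden width 1024 and batch size 512 when the gene count exceeds
#' 500, otherwise width 512 and batch size 2048; a 2-layer bidirectional LSTM
#' condition encoder with per-direction hidden size 128; AdamW at learning
#' rate 1e-4; KL weight 2.8 for low-dimensional (<= 500 genes) tasks and 0.02
#' above that; 1200 training epochs; a cosine schedule with offset 0.008.
#' `T` (diffusion steps) defaults to 1000.
#'
#' The `ablation` switch rewires the model: `"no_bilstm"` passes the raw
#' masked conditional through unchanged; `"no_xca"` swaps cross-covariance
#' attention for standard cell-axis self-attention; the two
#' `"diffusion_*_only"` variants keep a single auxiliary component *and* drop
#' the KL regularizer (weight forced to 0).
#'
#' @param nGenes number of genes (model input/output width).
#' @param width transformer hidden width; divisible by `nHeads`.
#' @param nBlocks,nHeads transformer depth and head count.
#' @param lstmHidden,lstmLayers condition encoder size.
#' @param T diffusion steps; `scheduleOffset` the cosine offset.
#' @param perturbSd s.d. of the training-time reference perturbation.
#' @param klWeight KL regularizer weight (alpha); `NULL` picks the
#'   dimensionality-dependent default.
#' @param learningRate,weightDecay,batchSize,epochs optimizer settings.
#' @param ablation one of `"full"`, `"no_bilstm"`, `"no_xca"`,
#'   `"diffusion_bilstm_only"`, `"diffusion_xca_only"`.
#' @param peephole use peephole LSTM gates as in the gate equations.
#' @param ffnMult FFN expansion factor.
#' @return A `modelConfig` list with derived fields `useBilstm`, `attention`.
#' @export
modelConfig <- function(nGenes, width = NULL, nBlocks = 6L, nHeads = 16L,
                        lstmHidden = 128L, lstmLayers = 2L, T = 1000L,
                        scheduleOffset = 0.008, perturbSd = 0.1,
                        klWeight = NULL, learningRate = 1e-4,
                        weightDecay = 0.01, batchSize = NULL, epochs = 1200L,
                        ablation = c("full", "no_bilstm", "no_xca",
                                     "diffusion_bilstm_only",
                                     "diffusion_xca_only"),
                        peephole = TRUE, ffnMult = 2L) {
  ablation <- match.arg(ablation)
  highDim <- nGenes > 500
  if (is.null(width)) width <- if (highDim) 1024L else 512L
  if (is.null(batchSize)) batchSize <- if (highDim) 512L else 2048L
  if (is.null(klWeight)) klWeight <- if (highDim) 0.02 else 2.8
  if (ablation %in% c("diffusion_bilstm_only", "diffusion_xca_only")) {
    klWeight <- 0
  }
  if (width %% nHeads != 0) stop("width must be divisible by nHeads")
  cfg <- list(nGenes = as.integer(nGenes), width = as.integer(width),
              nBlocks = as.integer(nBlocks), nHeads = as.integer(nHeads),
              lstmHidden = as.integer(lstmHidden),
              lstmLayers = as.integer(lstmLayers), T = as.integer(T),
              scheduleOffset = scheduleOffset, perturbSd = perturbSd,
              klWeight = klWeight, learningRate = learningRate,
              weightDecay = weightDecay, batchSize = as.integer(batchSize),
              epochs = as.integer(epochs), ablation = ablation,
              peephole = peephole, ffnMult = as.integer(ffnMult),
              useBilstm = !ablation %in% c("no_bilstm", "diffusion_xca_only"),
              attention = if (ablation %in% c("no_xca", "diffusion_bilstm_only"))
                "self" else "xca")
  class(cfg) <- "modelConfig"
  cfg
}

initBlockParams <- function(D, ffnMult) {
  lpiK <- function() {
    k <- matrix(0, 3, D)
    k[2, ] <- 1  # identity init: LPI starts as a no-op
    k
  }
  list(
    ln1 = list(g = rep(1, D), b = numeric(D)),
    att = list(Wq = xavier(D, D), Wk = xavier(D, D), Wv = xavier(D, D),
               Wo = xavier(D, D, gain = 0.5), bo = numeric(D)),
    ln2 = list(g = rep(1, D), b = numeric(D)),
    lpi = list(K1 = lpiK(), b1 = numeric(D), K2 = lpiK() * 0, b2 = numeric(D)),
    ln3 = list(g = rep(1, D), b = numeric(D)),
    ffn = list(W1 = xavier(D, ffnMult * D), b1 = numeric(ffnMult * D),
               W2 = xavier(ffnMult * D, D, gain = 0.5), b2 = numeric(D))
  )
}

initDenoiserParams <- function(cfg, seed = 0L) {
  withSeed(seed, {
    D <- cfg$width
    g <- cfg$nGenes
    p <- list(
      time = list(W1 = xavier(D, D), b1 = numeric(D),
                  W2 = xavier(D, D), b2 = numeric(D)),
      inp = list(W = xavier(g, D), b = numeric(D)),
      cond = list(W = xavier(g, D), b = numeric(D)),
      blocks = lapply(seq_len(cfg$nBlocks),
                      function(i) initBlockParams(D, cfg$ffnMult)),
      out = list(ln = list(g = rep(1, D), b = numeric(D)),
                 W = xavier(D, g, gain = 0.5), b = numeric(g))
    )
    if (cfg$useBilstm) {
      enc <- initConditionEncoder(g, cfg$lstmHidden, cfg$lstmLayers,
                                  seed = seed + 1L, peephole = cfg$peephole)
      p$enc <- enc$layers
      p$proj <- list(W = xavier(2L * cfg$lstmHidden, g), b = numeric(g))
    }
    p
  })
}

encoderStruct <- function(params, cfg) {
  list(layers = params$enc, hiddenSize = cfg$lstmHidden,
       nLayers = cfg$lstmLayers, inputWidth = cfg$nGenes,
       peephole = cfg$peephole)
}

#' Sinusoidal timestep embedding
#'
#' Encodes an integer timestep as interleaved sine/cosine features of the
#' requested (even) width, optionally refined by a two-layer MLP. The
#' embedding is a deterministic function of `t`.
#'
#' @param t timestep, `1 <= t <= Tmax`.
#' @param width embedding width (must be even).
#' @param Tmax upper bound on `t` (range check only).
#' @param mlp optional list `(W1, b1, W2, b2)` applied on top.
#' @return A numeric vector of length `width`.
#' @export
embedTime <- function(t, width, Tmax = Inf, mlp = NULL) {
  if (t < 1 || t > Tmax) stop("t out of range")
  pe <- sinusoidalEmbedding(t, width)
  if (is.null(mlp)) return(pe)
  a <- geluFwd(drop(pe %*% mlp$W1) + mlp$b1)
  drop(a %*% mlp$W2) + mlp$b2
}

#' Cross-covariance attention
#'
#' Attention along the feature (gene) axis: the attention map
#' `A = softmax(K'Q / sqrt(dk))` has shape `d x d` (one row/column per
#' feature), every column sums to 1, and the output is `V %*% A`, preserving
#' the cell dimension.
#'
#' @param Q,K,V matrices sharing the cell (row) dimension.
#' @param dk scaling dimension (> 0); defaults to `ncol(Q)`.
#' @return The output matrix with the attention map in
#'   `attr(, "attentionMap")`.
#' @export
xcAttention <- function(Q, K, V, dk = ncol(Q)) {
  if (dk <= 0) stop("dk must be > 0")
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V)) {
    stop("Q, K, V must share the cell dimension")
  }
  r <- xcaFwd(Q, K, V, dk)
  structure(r$O, attentionMap = r$A)
}

#' Standard self-attention (ablation fallback)
#'
#' Cell-axis attention `softmax(QK'/sqrt(dk)) V` with a row-stochastic
#' `cells x cells` map; used only when the configuration replaces
#' cross-covariance attention (`ablation = "no_xca"` or
#' `"diffusion_bilstm_only"`).
#'
#' @inheritParams xcAttention
#' @return The output matrix with the attention map in
#'   `attr(, "attentionMap")`.
#' @export
selfAttentionFallback <- function(Q, K, V, dk = ncol(Q)) {
  if (dk <= 0) stop("dk must be > 0")
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V)) {
    stop("Q, K, V must share the cell dimension")
  }
  r <- selfAttFwd(Q, K, V, dk)
  structure(r$O, attentionMap = r$A)
}

#' Local patch interaction block
#'
#' Depthwise local mixing along the feature (gene) axis with a width-3
#' window and edge-replicate padding: each feature is recombined with its two
#' neighbours using per-feature kernel weights. With `kernel2` supplied the
#' block is two such layers with a GELU between (the form used inside the
#' denoiser); with one layer and an identity kernel (centre row 1, others 0)
#' the block is the identity.
#'
#' @param x numeric matrix (cells x features), at least 3 features.
#' @param kernel,bias first layer: `3 x d` kernel and length-`d` bias.
#' @param kernel2,bias2 optional second layer.
#' @return Matrix of the same shape as `x`.
#' @export
lpiBlock <- function(x, kernel, bias = numeric(ncol(x)), kernel2 = NULL,
                     bias2 = numeric(ncol(x))) {
  if (ncol(x) < 3) stop("LPI window (3) larger than the feature count")
  stopifnot(nrow(kernel) == 3, ncol(kernel) == ncol(x))
  z <- dwConvFwd(x, kernel, bias)
  if (is.null(kernel2)) return(z)
  dwConvFwd(geluFwd(z), kernel2, bias2)
}

# ---- full network forward/backward --------------------------------------

headCols <- function(k, dh) (k - 1L) * dh + seq_len(dh)

netForward <- function(params, cfg, xtp, condRaw, t, keepCache = FALSE) {
  D <- cfg$width
  nh <- cfg$nHeads
  dh <- D %/% nh
  n <- nrow(xtp)
  cache <- if (keepCache) list() else NULL

  if (cfg$useBilstm) {
    encRes <- encoderFwd(condRaw, encoderStruct(params, cfg))
    yg <- linFwd(encRes$y, params$proj$W, params$proj$b)
    if (keepCache) cache$enc <- list(res = encRes, yg = yg)
  } else {
    yg <- condRaw
  }

  pe <- matrix(sinusoidalEmbedding(t, D), 1, D)
  t1 <- linFwd(pe, params$time$W1, params$time$b1)
  a1 <- geluFwd(t1)
  tv <- drop(linFwd(a1, params$time$W2, params$time$b2))
  if (keepCache) cache$time <- list(pe = pe, t1 = t1, a1 = a1)

  h <- linFwd(xtp, params$inp$W, params$inp$b)
  cnd <- linFwd(yg, params$cond$W, params$cond$b) + rowBroadcast(tv, n)
  if (keepCache) {
    cache$xtp <- xtp; cache$yg <- yg; cache$cnd <- cnd; cache$h0 <- h
    cache$blocks <- vector("list", cfg$nBlocks)
  }

  for (j in seq_len(cfg$nBlocks)) {
    bp <- params$blocks[[j]]
    bc <- if (keepCache) list() else NULL
    ln1 <- lnFwd(h, bp$ln1$g, bp$ln1$b)
    Q <- ln1$y %*% bp$att$Wq
    K <- cnd %*% bp$att$Wk
    V <- cnd %*% bp$att$Wv
    O <- matrix(0, n, D)
    heads <- if (keepCache) vector("list", nh) else NULL
    for (k in seq_len(nh)) {
      ix <- headCols(k, dh)
      r <- if (cfg$attention == "xca") {
        xcaFwd(Q[, ix, drop = FALSE], K[, ix, drop = FALSE],
               V[, ix, drop = FALSE], dh)
      } else {
        selfAttFwd(Q[, ix, drop = FALSE], K[, ix, drop = FALSE],
                   V[, ix, drop = FALSE], dh)
      }
      O[, ix] <- r$O
      if (keepCache) heads[[k]] <- r
    }
    attOut <- linFwd(O, bp$att$Wo, bp$att$bo)
    h <- h + attOut
    ln2 <- lnFwd(h, bp$ln2$g, bp$ln2$b)
    z1 <- dwConvFwd(ln2$y, bp$lpi$K1, bp$lpi$b1)
    a1b <- geluFwd(z1)
    z2 <- dwConvFwd(a1b, bp$lpi$K2, bp$lpi$b2)
    h <- h + z2
    ln3 <- lnFwd(h, bp$ln3$g, bp$ln3$b)
    f1 <- linFwd(ln3$y, bp$ffn$W1, bp$ffn$b1)
    af <- geluFwd(f1)
    f2 <- linFwd(af, bp$ffn$W2, bp$ffn$b2)
    h <- h + f2
    if (keepCache) {
      bc$ln1 <- ln1; bc$Q <- Q; bc$K <- K; bc$V <- V; bc$heads <- heads
      bc$O <- O; bc$ln2 <- ln2; bc$z1 <- z1; bc$a1 <- a1b; bc$ln3 <- ln3
      bc$f1 <- f1; bc$af <- af
      cache$blocks[[j]] <- bc
    }
  }

  lnF <- lnFwd(h, params$out$ln$g, params$out$ln$b)
  eps <- linFwd(lnF$y, params$out$W, params$out$b)
  if (keepCache) cache$lnF <- lnF
  list(eps = eps, cache = cache)
}

netBackward <- function(params, cfg, cache, dEps) {
  D <- cfg$width
  nh <- cfg$nHeads
  dh <- D %/% nh
  n <- nrow(dEps)
  gr <- list()

  lb <- linBwd(cache$lnF$y, params$out$W, dEps)
  gr$out <- list(W = lb$dW, b = lb$db)
  lnb <- lnBwd(cache$lnF, params$out$ln$g, lb$dx)
  gr$out$ln <- list(g = lnb$dg, b = lnb$db)
  dhm <- lnb$dx
  dcnd <- matrix(0, n, D)
  gr$blocks <- vector("list", cfg$nBlocks)

  for (j in rev(seq_len(cfg$nBlocks))) {
    bp <- params$blocks[[j]]
    bc <- cache$blocks[[j]]
    bg <- list()
    # FFN
    lb2 <- linBwd(bc$af, bp$ffn$W2, dhm)
    df1 <- geluBwd(bc$f1, lb2$dx)
    lb1 <- linBwd(bc$ln3$y, bp$ffn$W1, df1)
    bg$ffn <- list(W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db)
    lnb3 <- lnBwd(bc$ln3, bp$ln3$g, lb1$dx)
    bg$ln3 <- list(g = lnb3$dg, b = lnb3$db)
    dhm <- dhm + lnb3$dx
    # LPI
    cb2 <- dwConvBwd(bc$a1, bp$lpi$K2, dhm)
    dz1 <- geluBwd(bc$z1, cb2$dx)
    cb1 <- dwConvBwd(bc$ln2$y, bp$lpi$K1, dz1)
    bg$lpi <- list(K1 = cb1$dk, b1 = cb1$db, K2 = cb2$dk, b2 = cb2$db)
    lnb2 <- lnBwd(bc$ln2, bp$ln2$g, cb1$dx)
    bg$ln2 <- list(g = lnb2$dg, b = lnb2$db)
    dhm <- dhm + lnb2$dx
    # attention
    lbo <- linBwd(bc$O, bp$att$Wo, dhm)
    dQ <- matrix(0, n, D); dK <- matrix(0, n, D); dV <- matrix(0, n, D)
    for (k in seq_len(nh)) {
      ix <- headCols(k, dh)
      dOh <- lbo$dx[, ix, drop = FALSE]
      hb <- if (cfg$attention == "xca") {
        xcaBwd(bc$Q[, ix, drop = FALSE], bc$K[, ix, drop = FALSE],
               bc$V[, ix, drop = FALSE], dh, bc$heads[[k]], dOh)
      } else {
        selfAttBwd(bc$Q[, ix, drop = FALSE], bc$K[, ix, drop = FALSE],
                   bc$V[, ix, drop = FALSE], dh, bc$heads[[k]], dOh)
      }
      dQ[, ix] <- hb$dQ; dK[, ix] <- hb$dK; dV[, ix] <- hb$dV
    }
    bg$att <- list(Wq = crossprod(bc$ln1$y, dQ), Wk = crossprod(cache$cnd, dK),
                   Wv = crossprod(cache$cnd, dV), Wo = lbo$dW, bo = lbo$db)
    dcnd <- dcnd + dK %*% t(bp$att$Wk) + dV %*% t(bp$att$Wv)
    dln1y <- dQ %*% t(bp$att$Wq)
    lnb1 <- lnBwd(bc$ln1, bp$ln1$g, dln1y)
    bg$ln1 <- list(g = lnb1$dg, b = lnb1$db)
    dhm <- dhm + lnb1$dx
    gr$blocks[[j]] <- bg
  }

  # input embedding
  lbin <- linBwd(cache$xtp, params$inp$W, dhm)
  gr$inp <- list(W = lbin$dW, b = lbin$db)
  # condition embedding and time MLP
  lbc <- linBwd(cache$yg, params$cond$W, dcnd)
  gr$cond <- list(W = lbc$dW, b = lbc$db)
  dtv <- matrix(colSums(dcnd), 1)
  lbt2 <- linBwd(cache$time$a1, params$time$W2, dtv)
  dt1 <- geluBwd(cache$time$t1, lbt2$dx)
  lbt1 <- linBwd(cache$time$pe, params$time$W1, dt1)
  gr$time <- list(W1 = lbt1$dW, b1 = lbt1$db, W2 = lbt2$dW, b2 = lbt2$db)

  if (cfg$useBilstm) {
    lbp <- linBwd(cache$enc$res$y, params$proj$W, lbc$dx)
    gr$proj <- list(W = lbp$dW, b = lbp$db)
    eb <- encoderBwd(encoderStruct(params, cfg), cache$enc$res$caches, lbp$dx)
    gr$enc <- lapply(eb$layerGrads, function(lg) {
      list(fw = list(Wx = lg$fw$dWx, Wh = lg$fw$dWh, b = lg$fw$db,
                     pi = lg$fw$dpi, pf = lg$fw$dpf, po = lg$fw$dpo),
           bw = list(Wx = lg$bw$dWx, Wh = lg$bw$dWh, b = lg$bw$db,
                     pi = lg$bw$dpi, pf = lg$bw$dpf, po = lg$bw$dpo))
    })
  }
  gr
}

#' Run the denoiser on a composed input
#'
#' Predicts the noise in `xIn` given the raw masked conditional matrix
#' (encoded by the model's condition path) and the timestep. Mostly useful
#' for inspection; training and imputation call this internally.
#'
#' @param model a `diffusionModel` (from [diffusionModel()] or
#'   [trainModel()]).
#' @param xIn composed input matrix (cells x genes, standardized scale).
#' @param cond masked conditional matrix, same shape.
#' @param t timestep in `1..T`.
#' @return The predicted-noise matrix, same shape as `xIn`.
#' @export
denoiserForward <- function(model, xIn, cond, t) {
  stopifnot(inherits(model, "diffusionModel"))
  if (!identical(dim(xIn), dim(cond))) stop("xIn and cond shapes differ")
  if (ncol(xIn) != model$cfg$nGenes) stop("gene width mismatch with model")
  netForward(model$params, model$cfg, xIn, cond, t)$eps
}

#' Construct an untrained diffusion imputation model
#'
#' @param nGenes gene count (reference gene axis).
#' @param cfg a [modelConfig()]; defaults to `modelConfig(nGenes)`.
#' @param seed seed for weight initialization.
#' @return A `diffusionModel` list: `params`, `cfg`, `schedule`.
#' @export
diffusionModel <- function(nGenes, cfg = modelConfig(nGenes), seed = 0L) {
  stopifnot(inherits(cfg, "modelConfig"))
  structure(list(params = initDenoiserParams(cfg, subSeed(seed, "init")),
                 cfg = cfg,
                 schedule = buildCosineSchedule(cfg$T, cfg$scheduleOffset)),
            class = "diffusionModel")
}

#' @exportS3Method base::print
print.diffusionModel <- function(x, ...) {
  cat(sprintf("diffusionModel: %d genes, width %d, %d blocks x %d heads, T = %d\n",
              x$cfg$nGenes, x$cfg$width, x$cfg$nBlocks, x$cfg$nHeads, x$cfg$T))
  cat(sprintf("  condition path: %s; attention: %s; ablation: %s\n",
              if (x$cfg$useBilstm) {
                sprintf("BiLSTM (%d x %d)", x$cfg$lstmLayers, x$cfg$lstmHidden)
              } else "identity",
              x$cfg$attention, x$cfg$ablation))
  if (!is.null(x$trace)) {
    cat(sprintf("  trained: %d iterations, final loss %.4f\n",
                nrow(x$trace), x$trace$total[nrow(x$trace)]))
  }
  invisible(x)
}
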