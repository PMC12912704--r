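# Bidirectional peephole-LSTM condition encoder.
#
# The masked conditional matrix is read as a sequence of cells, forward and
# backward; the concatenated hidden states form the enriched condition
# representation fed to the denoiser. Gates follow the peephole formulation:
# the input and forget gates see the previous cell state, the output gate the
# current one. Internally the four gates are packed into single (in x 4H) /
# (H x 4H) weight matrices so each sequence step costs a handful of
# matrix-vector products; gradients are accumulated by explicit backprop
# through time.

#' One peephole-LSTM cell step
#'
#' Computes the five gate equations for a single timestep: input gate
#' `i = sigmoid(Wxi y + Whi h + Wci c + bi)`, forget gate
#' `f = sigmoid(Wxf y + Whf h + Wcf c + bf)`, cell update
#' `c' = f*c + i*tanh(Wxc y + Whc h + bc)`, output gate
#' `o = sigmoid(Wxo y + Who h + Wco c' + bo)`, and `h' = o * tanh(c')`.
#' Peephole weights (`Wci`, `Wcf`, `Wco`) are element-wise (diagonal)
#' vectors.
#'
#' @param y input vector for this step.
#' @param hPrev,cPrev previous hidden and cell state vectors (length H).
#' @param params list with matrices `Wxi, Whi, Wxf, Whf, Wxc, Whc, Wxo, Who`
#'   (input width x H and H x H), peephole vectors `Wci, Wcf, Wco` and biases
#'   `bi, bf, bc, bo` (length H).
#' @return `list(h, c)` — the new hidden and cell state.
#' @export
lstmCellStep <- function(y, hPrev, cPrev, params) {
  if (any(!is.finite(y)) || any(!is.finite(hPrev)) || any(!is.finite(cPrev))) {
    stop("non-finite input to lstmCellStep")
  }
  p <- params
  sig <- stats::plogis
  i <- sig(drop(y %*% p$Wxi + hPrev %*% p$Whi) + p$Wci * cPrev + p$bi)
  f <- sig(drop(y %*% p$Wxf + hPrev %*% p$Whf) + p$Wcf * cPrev + p$bf)
  cNew <- f * cPrev + i * tanh(drop(y %*% p$Wxc + hPrev %*% p$Whc) + p$bc)
  o <- sig(drop(y %*% p$Wxo + hPrev %*% p$Who) + p$Wco * cNew + p$bo)
  list(h = o * tanh(cNew), c = cNew)
}

# ---- packed single-direction LSTM --------------------------------------

# Gate column blocks in the packed (.. x 4H) matrices: i, f, g (cell
# candidate), o.
gateIdx <- function(H) {
  list(i = seq_len(H), f = H + seq_len(H), g = 2L * H + seq_len(H),
       o = 3L * H + seq_len(H))
}

initLstmWeights <- function(inWidth, H) {
  Wx <- xavier(inWidth, 4L * H)
  Wh <- xavier(H, 4L * H)
  b <- numeric(4L * H)
  b[gateIdx(H)$f] <- 1  # open forget gate at init
  list(Wx = Wx, Wh = Wh, b = b,
       pi = numeric(H), pf = numeric(H), po = numeric(H))
}

lstmDirFwd <- function(X, w, peephole = TRUE) {
  n <- nrow(X)
  H <- length(w$pi)
  gi <- gateIdx(H)
  preX <- X %*% w$Wx + rowBroadcast(w$b, n)
  Hm <- matrix(0, n, H); Hprev <- matrix(0, n, H)
  I <- matrix(0, n, H); Fg <- matrix(0, n, H); G <- matrix(0, n, H)
  O <- matrix(0, n, H); Cprev <- matrix(0, n, H); C <- matrix(0, n, H)
  h <- numeric(H); cv <- numeric(H)
  sig <- stats::plogis
  for (t in seq_len(n)) {
    hw <- drop(h %*% w$Wh)
    pre <- preX[t, ] + hw
    i <- sig(pre[gi$i] + if (peephole) w$pi * cv else 0)
    f <- sig(pre[gi$f] + if (peephole) w$pf * cv else 0)
    g <- tanh(pre[gi$g])
    Hprev[t, ] <- h; Cprev[t, ] <- cv
    cn <- f * cv + i * g
    o <- sig(pre[gi$o] + if (peephole) w$po * cn else 0)
    h <- o * tanh(cn)
    I[t, ] <- i; Fg[t, ] <- f; G[t, ] <- g; O[t, ] <- o
    C[t, ] <- cn; Hm[t, ] <- h
    cv <- cn
  }
  list(H = Hm, cache = list(X = X, I = I, F = Fg, G = G, O = O,
                            Cprev = Cprev, C = C, Hprev = Hprev,
                            peephole = peephole))
}

lstmDirBwd <- function(w, cache, dH) {
  n <- nrow(dH)
  H <- length(w$pi)
  gi <- gateIdx(H)
  A <- matrix(0, n, 4L * H)
  peep <- cache$peephole
  dhrec <- numeric(H); dc <- numeric(H)
  tWh <- t(w$Wh)
  for (t in rev(seq_len(n))) {
    dh <- dH[t, ] + dhrec
    tc <- tanh(cache$C[t, ])
    o <- cache$O[t, ]
    doPre <- dh * tc * o * (1 - o)
    dc <- dc + dh * o * (1 - tc * tc) + if (peep) doPre * w$po else 0
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]
    cp <- cache$Cprev[t, ]
    diPre <- dc * g * i * (1 - i)
    dfPre <- dc * cp * f * (1 - f)
    dgPre <- dc * i * (1 - g * g)
    a <- c(diPre, dfPre, dgPre, doPre)
    A[t, ] <- a
    dhrec <- drop(a %*% tWh)
    dc <- dc * f + if (peep) diPre * w$pi + dfPre * w$pf else 0
  }
  g <- list(
    dWx = crossprod(cache$X, A), dWh = crossprod(cache$Hprev, A),
    db = colSums(A),
    dpi = if (peep) colSums(A[, gi$i, drop = FALSE] * cache$Cprev) else numeric(H),
    dpf = if (peep) colSums(A[, gi$f, drop = FALSE] * cache$Cprev) else numeric(H),
    dpo = if (peep) colSums(A[, gi$o, drop = FALSE] * cache$C) else numeric(H),
    dX = A %*% t(w$Wx))
  g
}

# ---- stacked bidirectional encoder -------------------------------------

#' Initialise a bidirectional condition encoder
#'
#' @param inputWidth width of each sequence element (number of genes).
#' @param hiddenSize per-direction hidden width (default 128).
#' @param nLayers number of stacked bidirectional layers (default 2).
#' @param seed integer seed for the weight draw.
#' @param peephole use peephole gate terms (default TRUE).
#' @return An encoder parameter list; pass to [encodeCondition()].
#' @export
initConditionEncoder <- function(inputWidth, hiddenSize = 128L, nLayers = 2L,
                                 seed = 0L, peephole = TRUE) {
  withSeed(seed, {
    layers <- vector("list", nLayers)
    inw <- inputWidth
    for (l in seq_len(nLayers)) {
      layers[[l]] <- list(fw = initLstmWeights(inw, hiddenSize),
                          bw = initLstmWeights(inw, hiddenSize))
      inw <- 2L * hiddenSize
    }
    list(layers = layers, hiddenSize = as.integer(hiddenSize),
         nLayers = as.integer(nLayers), inputWidth = as.integer(inputWidth),
         peephole = peephole)
  })
}

encoderFwd <- function(X, enc) {
  caches <- vector("list", enc$nLayers)
  cur <- X
  for (l in seq_len(enc$nLayers)) {
    w <- enc$layers[[l]]
    fw <- lstmDirFwd(cur, w$fw, enc$peephole)
    bw <- lstmDirFwd(cur[rev(seq_len(nrow(cur))), , drop = FALSE], w$bw,
                     enc$peephole)
    caches[[l]] <- list(fw = fw$cache, bw = bw$cache)
    cur <- cbind(fw$H, bw$H[rev(seq_len(nrow(bw$H))), , drop = FALSE])
  }
  list(y = cur, caches = caches)
}

encoderBwd <- function(enc, caches, dY) {
  H <- enc$hiddenSize
  grads <- vector("list", enc$nLayers)
  d <- dY
  for (l in rev(seq_len(enc$nLayers))) {
    w <- enc$layers[[l]]
    n <- nrow(d)
    dfw <- d[, seq_len(H), drop = FALSE]
    dbw <- d[rev(seq_len(n)), H + seq_len(H), drop = FALSE]
    gf <- lstmDirBwd(w$fw, caches[[l]]$fw, dfw)
    gb <- lstmDirBwd(w$bw, caches[[l]]$bw, dbw)
    dX <- gf$dX + gb$dX[rev(seq_len(n)), , drop = FALSE]
    grads[[l]] <- list(fw = gf[c("dWx", "dWh", "db", "dpi", "dpf", "dpo")],
                       bw = gb[c("dWx", "dWh", "db", "dpi", "dpf", "dpo")])
    d <- dX
  }
  list(layerGrads = grads, dX = d)
}

#' Encode the masked conditional matrix
#'
#' Runs the stacked bidirectional encoder over the cell sequence (rows of
#' `cond`, in their given order) and concatenates the forward and backward
#' hidden state of every cell: the output has `2 * hiddenSize` columns. The
#' result is a deterministic function of `(cond, encoder)`.
#'
#' @param cond numeric matrix (cells x genes) or [ExpressionMatrix-class].
#' @param encoder parameters from [initConditionEncoder()].
#' @return Matrix `y'` of dimension cells x `2 * hiddenSize`.
#' @export
encodeCondition <- function(cond, encoder) {
  if (is(cond, "ExpressionMatrix")) cond <- cond@values
  if (!is.matrix(cond) || nrow(cond) < 1L) stop("cond must be a non-empty matrix")
  if (ncol(cond) != encoder$inputWidth) {
    stop("cond width does not match encoder inputWidth")
  }
  encoderFwd(cond, encoder)$y
}
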