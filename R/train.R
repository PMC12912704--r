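#' Train the conditional diffusion model on a reference matrix
#'
#' One training iteration: sample a batch of reference cells, perturb them
#' with Gaussian noise, draw a timestep `t ~ U(1,T)` and noise `eps`, diffuse
#' to `x_t`, splice shared-gene entries from the perturbed clean data with
#' unique-gene entries from `x_t`, encode the masked conditional, predict the
#' noise, and take one AdamW step on the masked MSE + KL loss. Expression is
#' standardized per gene (mean 0, s.d. 1, statistics stored in the model) so
#' the variance-preserving diffusion operates on the scale it assumes.
#'
#' @param reference an [ExpressionMatrix-class] (already on the working
#'   scale; see [normalizeExpression()]).
#' @param mask a [GeneMask-class] with at least one shared and one unique
#'   column.
#' @param cfg a [modelConfig()].
#' @param nIter number of optimizer iterations; defaults to
#'   `cfg$epochs * ceiling(nCells / batch)`.
#' @param seed master seed (weights, batches, noise draws).
#' @param init optional `diffusionModel` to warm-start from (fine-tuning).
#' @param verbose print a loss line every 200 iterations.
#' @return A trained `diffusionModel`: parameters, config, schedule, per-gene
#'   standardization stats, the training mask, and the loss trace
#'   (`data.frame` with `iter`, `mse`, `kl`, `total`).
#' @export
trainModel <- function(reference, mask, cfg, nIter = NULL, seed = 0L,
                       init = NULL, verbose = FALSE) {
  stopifnot(is(reference, "ExpressionMatrix"), is(mask, "GeneMask"),
            inherits(cfg, "modelConfig"))
  X <- reference@values
  g <- ncol(X)
  if (g != cfg$nGenes) stop("cfg$nGenes does not match the reference")
  if (!identical(mask@geneNames, reference@geneNames)) {
    stop("mask gene axis must match the reference")
  }
  mCol <- as.numeric(mask@geneNames %in% mask@sharedGenes)
  if (all(mCol == 1) || all(mCol == 0)) {
    stop("training needs both shared and unique genes")
  }
  n <- nrow(X)
  b <- min(cfg$batchSize, n)
  if (is.null(nIter)) nIter <- cfg$epochs * ceiling(n / b)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")

  model <- if (is.null(init)) {
    diffusionModel(g, cfg, seed)
  } else {
    stopifnot(inherits(init, "diffusionModel"))
    init
  }
  params <- model$params
  sched <- model$schedule
  state <- adamInit(params)
  mB <- matrix(rep(mCol, each = b), b, g)
  trace <- matrix(NA_real_, nIter, 4L,
                  dimnames = list(NULL, c("iter", "mse", "kl", "total")))

  set.seed(subSeed(seed, "noise"))
  for (it in seq_len(nIter)) {
    idx <- if (b < n) sample.int(n, b) else seq_len(n)
    x0 <- Z[idx, , drop = FALSE]
    x0h <- x0 + matrix(stats::rnorm(b * g, 0, cfg$perturbSd), b, g)
    t <- sample.int(sched@T, 1L)
    epsm <- matrix(stats::rnorm(b * g), b, g)
    xt <- forwardDiffuse(x0h, t, epsm, sched)
    xtp <- x0h * mB + xt * (1 - mB)
    condRaw <- x0h * mB
    fwd <- netForward(params, cfg, xtp, condRaw, t, keepCache = TRUE)
    lb <- trainingLoss(epsm, fwd$eps, mB, cfg$klWeight)
    if (!is.finite(lb$total)) {
      stop(sprintf("training diverged at iteration %d (loss = %g); lower the learning rate",
                   it, lb$total))
    }
    trace[it, ] <- c(it, lb$mse, lb$kl, lb$total)
    dEps <- lossGrad(epsm, fwd$eps, mB, cfg$klWeight)
    gr <- netBackward(params, cfg, fwd$cache, dEps)
    up <- adamUpdate(params, gr, state, cfg$learningRate, cfg$weightDecay)
    params <- up$params
    state <- up$state
    if (verbose && it %% 200L == 0L) {
      message(sprintf("iter %6d  mse %.4f  kl %.4f  total %.4f",
                      it, lb$mse, lb$kl, lb$total))
    }
  }

  model$params <- params
  model$geneStats <- list(mu = mu, sd = sdv)
  model$mask <- mask
  model$geneNames <- reference@geneNames
  model$trace <- as.data.frame(trace)
  model$seed <- seed
  model
}

#' Impute unmeasured genes in an ST matrix
#'
#' Builds the conditional vector by zero-filling the unique-gene component,
#' draws `x_T ~ N(0, I)` on the unique entries, and runs the learned reverse
#' chain: at every step the state is re-composed with the conditional through
#' the mask, the condition encoding (computed once; it does not change across
#' steps) and the timestep feed the denoiser, and the predicted noise drives
#' the reverse update. With `nDraws > 1` the returned point prediction is the
#' average of several independent reverse trajectories, which reduces sampler
#' variance. Output shared-gene columns carry the conditional's measured
#' values exactly; imputed values are clipped at zero.
#'
#' @param st [ExpressionMatrix-class] with the measured (shared) genes, on
#'   the model's working scale.
#' @param model a trained `diffusionModel` from [trainModel()].
#' @param nSteps reverse steps; `model$cfg$T` (default) runs the full chain,
#'   smaller values stride the schedule.
#' @param seed sampler seed; the draw is deterministic given it.
#' @param nDraws number of averaged reverse trajectories (default 1).
#' @param x0Clip stability bound: at every reverse step the implied clean
#'   signal `(x_t - sqrt(1-gamma) epsHat) / sqrt(gamma)` is clipped to
#'   `[-x0Clip, x0Clip]` (standardized scale) before the posterior-mean
#'   update — the usual static-thresholding guard that keeps late-schedule
#'   steps (where `1/sqrt(alpha_t)` is large) from amplifying prediction
#'   error.
#' @return [ExpressionMatrix-class] over all model genes x ST cells.
#' @export
imputeExpression <- function(st, model, nSteps = model$cfg$T, seed = 0L,
                             nDraws = 1L, x0Clip = 8) {
  stopifnot(is(st, "ExpressionMatrix"), inherits(model, "diffusionModel"))
  if (is.null(model$geneStats)) stop("model has not been trained")
  genes <- model$geneNames
  shared <- intersect(genes, st@geneNames)
  shared <- intersect(shared, model$mask@sharedGenes)
  if (!length(shared)) stop("no shared genes between the ST matrix and the model")
  n <- nrow(st@values)
  g <- length(genes)
  y <- matrix(0, n, g, dimnames = list(st@cellNames, genes))
  y[, shared] <- st@values[, shared]
  yz <- sweep(sweep(y, 2, model$geneStats$mu, "-"), 2, model$geneStats$sd, "/")
  mCol <- as.numeric(genes %in% shared)
  mB <- matrix(rep(mCol, each = n), n, g)
  yz <- yz * mB  # zero-fill the unique component on the standardized scale
  condRaw <- yz
  cfg <- model$cfg
  sched <- model$schedule

  ygPre <- if (cfg$useBilstm) {
    linFwd(encoderFwd(condRaw, encoderStruct(model$params, cfg))$y,
           model$params$proj$W, model$params$proj$b)
  } else condRaw

  Tn <- sched@T
  nSteps <- max(1L, min(as.integer(nSteps), Tn))
  times <- unique(round(seq(Tn, 1, length.out = nSteps)))
  gamma0 <- c(1, sched@gamma)  # gamma[0] = 1

  acc <- matrix(0, n, g)
  set.seed(subSeed(seed, "sampler"))
  for (d in seq_len(nDraws)) {
    x <- matrix(stats::rnorm(n * g), n, g)
    for (k in seq_along(times)) {
      t <- times[k]
      tPrev <- if (k < length(times)) times[k + 1L] else 0L
      xtp <- yz * mB + x * (1 - mB)
      epsHat <- netForwardCached(model$params, cfg, xtp, ygPre, t)
      gm <- sched@gamma[t]
      # static thresholding: bound the implied x0, refold into a noise
      # estimate, then take the usual posterior-mean step
      x0Hat <- pmin(pmax((xtp - sqrt(1 - gm) * epsHat) / sqrt(gm), -x0Clip),
                    x0Clip)
      epsTilde <- (xtp - sqrt(gm) * x0Hat) / sqrt(1 - gm)
      aEff <- gm / gamma0[tPrev + 1L]
      epsT <- if (tPrev > 0L) matrix(stats::rnorm(n * g), n, g) else 0
      x <- (xtp - (1 - aEff) / sqrt(1 - gm) * epsTilde) / sqrt(aEff) +
        sqrt(1 - aEff) * epsT
    }
    acc <- acc + (yz * mB + x * (1 - mB))
  }
  xz <- acc / nDraws
  vals <- sweep(sweep(xz, 2, model$geneStats$sd, "*"), 2,
                model$geneStats$mu, "+")
  vals <- pmax(vals, 0)
  vals[, shared] <- y[, shared]  # measured values pass through untouched
  ExpressionMatrix(vals, genes, st@cellNames, "st")
}

# Forward pass with a precomputed condition-path output (the condition does
# not change across reverse steps, so the encoder runs once per trajectory).
netForwardCached <- function(params, cfg, xtp, ygPre, t) {
  cfgNoEnc <- cfg
  cfgNoEnc$useBilstm <- FALSE
  netForward(params, cfgNoEnc, xtp, ygPre, t)$eps
}

#' Gene-holdout cross-validation of imputation accuracy
#'
#' Splits the shared genes into `k` folds; in each fold the assigned genes
#' are re-labelled unique (dropped from the ST conditional), the model is
#' trained (from scratch by default, or fine-tuned from a shared backbone),
#' the fold genes are imputed, and their imputed values are scored against
#' the measured ST values with the four gene-level metrics. Every shared gene
#' is scored exactly once, and never while it conditions the model.
#'
#' @param reference,st [ExpressionMatrix-class] pair on the working scale.
#' @param k fold count (default 5).
#' @param cfg a [modelConfig()].
#' @param nIter training iterations per fold.
#' @param seed master seed (fold split, training, sampler).
#' @param nDraws reverse trajectories averaged per imputation.
#' @param mode `"retrain"` (default: per-fold training from scratch, no
#'   leakage across folds) or `"finetune"` (one backbone trained on the full
#'   mask, then `nIterFinetune` iterations per fold; faster, reported as
#'   such).
#' @param nIterFinetune fine-tuning iterations when `mode = "finetune"`.
#' @return An `EvalReport` list: `perGene` (data.frame with gene, fold, spcc,
#'   ssim, rmse, js), `summary` (means), `mode`, `k`.
#' @export
runCrossval <- function(reference, st, k = 5L, cfg, nIter = NULL, seed = 0L,
                        nDraws = 1L, mode = c("retrain", "finetune"),
                        nIterFinetune = 200L) {
  mode <- match.arg(mode)
  mask <- buildGeneMask(reference, st)
  plan <- makeCVSplits(mask, k, subSeed(seed, "folds"))
  base <- if (mode == "finetune") {
    trainModel(reference, mask, cfg, nIter, seed)
  } else NULL

  rows <- list()
  for (f in seq_len(plan@k) - 1L) {
    heldOut <- names(plan@foldAssignments)[plan@foldAssignments == f]
    foldMask <- dropSharedGenes(mask, heldOut)
    condGenes <- intersect(st@geneNames, foldMask@sharedGenes)
    stCond <- ExpressionMatrix(st@values[, condGenes, drop = FALSE],
                               condGenes, st@cellNames, "st")
    model <- if (mode == "retrain") {
      trainModel(reference, foldMask, cfg, nIter, seed + f)
    } else {
      m <- base; m$mask <- foldMask
      trainModel(reference, foldMask, cfg, nIterFinetune, seed + f, init = m)
    }
    imp <- imputeExpression(stCond, model, seed = seed + f, nDraws = nDraws)
    for (gene in heldOut) {
      pred <- imp@values[, gene]
      truth <- st@values[, gene]
      rows[[gene]] <- data.frame(
        gene = gene, fold = f,
        spcc = spccGene(pred, truth), ssim = ssimGene(pred, truth),
        rmse = rmseGene(pred, truth), js = jsGene(pred, truth))
    }
  }
  perGene <- do.call(rbind, rows)
  rownames(perGene) <- NULL
  list(perGene = perGene,
       summary = colMeans(perGene[, c("spcc", "ssim", "rmse", "js")],
                          na.rm = TRUE),
       mode = mode, k = plan@k)
}
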