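#' Configuration for the paired-data simulator
#'
#' The generator emulates the statistical situation the imputation model
#' assumes: two modalities drawn from the same tissue, sharing a latent
#' gene-module dependency structure, where the ST matrix measures only a
#' fraction of the genes. Expression follows a rectified linear factor model:
#' each gene loads dominantly on one of `nModules` latent programs (plus
#' small secondary loadings on the others), module activities are
#' cell-type-specific with per-cell variability, and Gaussian measurement
#' noise is added before rectification at zero. Values are generated directly
#' on a normalized log-like scale.
#'
#' Defaults are the desk-scale study conditions used throughout the package's
#' own evaluation: 200 reference cells, 100 ST cells, 50 genes, 4 modules,
#' 70% shared genes, noise s.d. 0.05, no batch shift, no dropout.
#'
#' @param nRefCells,nStCells,nGenes,nModules,nCelltypes counts.
#' @param sharedFraction fraction of genes measured in the ST modality, in
#'   (0,1).
#' @param batchShift scale (log-space, additive) of the per-gene batch offset
#'   applied to the *reference* modality; 0 disables it.
#' @param dropoutRate probability that an ST entry is zeroed independently,
#'   in \[0,1).
#' @param noiseSd s.d. of the Gaussian measurement noise (>0).
#' @param activitySd per-cell s.d. of module activities around their
#'   cell-type mean.
#' @param secondaryLoadingSd s.d. of the small off-module loadings that make
#'   gene ranks depend on more than one program.
#' @param spatialPatterns optional list of `list(gene=<index>,
#'   pattern=<"stripe_h"|"stripe_v"|"blob"|"band">)` planted into the ST
#'   modality.
#' @param patternAmplitude multiplicative boost of a pattern gene inside its
#'   active region.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return A validated `simConfig` list.
#' @export
simConfig <- function(nRefCells = 200L, nStCells = 100L, nGenes = 50L,
                      nModules = 4L, sharedFraction = 0.7, batchShift = 0,
                      dropoutRate = 0, noiseSd = 0.05, nCelltypes = 3L,
                      activitySd = 0.3, secondaryLoadingSd = 0.25,
                      spatialPatterns = NULL, patternAmplitude = 3,
                      seed = 1L) {
  cfg <- list(nRefCells = as.integer(nRefCells), nStCells = as.integer(nStCells),
              nGenes = as.integer(nGenes), nModules = as.integer(nModules),
              sharedFraction = sharedFraction, batchShift = batchShift,
              dropoutRate = dropoutRate, noiseSd = noiseSd,
              nCelltypes = as.integer(nCelltypes), activitySd = activitySd,
              secondaryLoadingSd = secondaryLoadingSd,
              spatialPatterns = spatialPatterns,
              patternAmplitude = patternAmplitude, seed = as.integer(seed))
  if (cfg$sharedFraction <= 0 || cfg$sharedFraction >= 1) {
    stop("sharedFraction must lie in (0,1)")
  }
  if (cfg$sharedFraction * cfg$nGenes < 2) {
    stop("sharedFraction * nGenes must be >= 2")
  }
  if (cfg$nModules > cfg$nGenes) stop("nModules must not exceed nGenes")
  if (cfg$dropoutRate < 0 || cfg$dropoutRate >= 1) {
    stop("dropoutRate must lie in [0,1)")
  }
  if (cfg$noiseSd <= 0) stop("noiseSd must be > 0")
  if (cfg$batchShift < 0) stop("batchShift must be >= 0")
  for (p in cfg$spatialPatterns) {
    if (!p$pattern %in% c("stripe_h", "stripe_v", "blob", "band")) {
      stop("unknown spatial pattern: ", p$pattern)
    }
    if (p$gene < 1 || p$gene > cfg$nGenes) stop("pattern gene index out of range")
  }
  class(cfg) <- "simConfig"
  cfg
}

# Draw one modality from the shared factor model.
drawModality <- function(nCells, loadings, typeMeans, cfg, prefix) {
  types <- sample.int(cfg$nCelltypes, nCells, replace = TRUE)
  act <- typeMeans[types, , drop = FALSE] +
    matrix(stats::rnorm(nCells * cfg$nModules, 0, cfg$activitySd),
           nCells, cfg$nModules)
  x <- act %*% t(loadings) +
    matrix(stats::rnorm(nCells * cfg$nGenes, 0, cfg$noiseSd),
           nCells, cfg$nGenes)
  x <- pmax(x, 0)
  rownames(x) <- paste0(prefix, seq_len(nCells))
  list(x = x, types = types)
}

patternRegion <- function(pattern, coords) {
  switch(pattern,
    stripe_v = coords[, 1] >= 0.5,
    stripe_h = coords[, 2] >= 0.5,
    blob = sqrt((coords[, 1] - 0.5)^2 + (coords[, 2] - 0.5)^2) < 0.3,
    band = abs(coords[, 1] + coords[, 2] - 1) < 0.2,
    stop("unknown pattern"))
}

#' Simulate a paired scRNA-seq reference and ST dataset
#'
#' Draws a reference matrix, a fully measured ST ground truth (`stTruth`,
#' same loadings and cell-type profiles as the reference), and the observed
#' ST matrix (`stObserved`): `stTruth` restricted to a `sharedFraction`
#' subset of genes with optional independent dropout. When `batchShift > 0`
#' the reference is displaced by per-gene additive offsets, emulating the
#' modality-level batch effect that imputation must not inherit.
#'
#' @param cfg a [simConfig()].
#' @return A list with elements `reference`, `stTruth`, `stObserved` (all
#'   [ExpressionMatrix-class]), `labels` (ST cell types), `refLabels`,
#'   `coords` (ST cell coordinates on the unit square), `modules` (dominant
#'   module per gene), `batchOffsets`, and `config`.
#' @examples
#' sim <- simulatePair(simConfig(nRefCells = 40, nStCells = 20, nGenes = 12,
#'                               nModules = 2, seed = 7))
#' sim$reference
#' @export
simulatePair <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  withSeed(subSeed(cfg$seed, "simulate"), {
    g <- cfg$nGenes
    modules <- ((seq_len(g) - 1L) %% cfg$nModules) + 1L
    loadings <- matrix(stats::rnorm(g * cfg$nModules, 0,
                                    cfg$secondaryLoadingSd),
                       g, cfg$nModules)
    loadings[cbind(seq_len(g), modules)] <- stats::runif(g, 0.7, 1.3)
    typeMeans <- matrix(stats::runif(cfg$nCelltypes * cfg$nModules, 0.5, 2),
                        cfg$nCelltypes, cfg$nModules)
    geneNamesAll <- sprintf("gene_%03d", seq_len(g))
    nShared <- ceiling(cfg$sharedFraction * g)
    sharedIdx <- sort(sample.int(g, nShared))

    ref <- drawModality(cfg$nRefCells, loadings, typeMeans, cfg, "ref_")
    st <- drawModality(cfg$nStCells, loadings, typeMeans, cfg, "st_")

    offsets <- numeric(g)
    if (cfg$batchShift > 0) {
      offsets <- cfg$batchShift * stats::runif(g, 0.5, 1.5)
      ref$x <- sweep(ref$x, 2, offsets, "+")
    }

    coords <- cbind(x = stats::runif(cfg$nStCells),
                    y = stats::runif(cfg$nStCells))
    for (p in cfg$spatialPatterns) {
      inside <- patternRegion(p$pattern, coords)
      st$x[inside, p$gene] <- st$x[inside, p$gene] * (1 + cfg$patternAmplitude)
    }

    obs <- st$x[, sharedIdx, drop = FALSE]
    if (cfg$dropoutRate > 0) {
      keep <- matrix(stats::runif(length(obs)) >= cfg$dropoutRate,
                     nrow(obs), ncol(obs))
      obs <- obs * keep
    }

    list(
      reference = ExpressionMatrix(ref$x, geneNamesAll, rownames(ref$x), "scrna"),
      stTruth = ExpressionMatrix(st$x, geneNamesAll, rownames(st$x), "st"),
      stObserved = ExpressionMatrix(obs, geneNamesAll[sharedIdx],
                                    rownames(st$x), "st"),
      labels = st$types, refLabels = ref$types, coords = coords,
      modules = stats::setNames(modules, geneNamesAll),
      batchOffsets = stats::setNames(offsets, geneNamesAll),
      config = cfg
    )
  })
}

#' Within- vs between-module correlation of a simulated matrix
#'
#' Sanity check that the generator planted the dependency structure the
#' imputation model relies on: genes sharing a module should be markedly more
#' correlated than genes in different modules.
#'
#' @param x an [ExpressionMatrix-class] (typically `sim$reference`).
#' @param modules integer module assignment per gene (as in
#'   `simulatePair()$modules`).
#' @return A list with `within` and `between` mean absolute pairwise
#'   correlations (`between` is `NA` when there is a single module) and the
#'   per-module means `perModule`.
#' @export
plantedCorrelationCheck <- function(x, modules) {
  stopifnot(is(x, "ExpressionMatrix"), length(modules) == ncol(x@values))
  r <- abs(stats::cor(x@values))
  diag(r) <- NA
  same <- outer(modules, modules, "==")
  within <- mean(r[same], na.rm = TRUE)
  between <- if (length(unique(modules)) > 1L) mean(r[!same], na.rm = TRUE) else NA_real_
  perModule <- vapply(sort(unique(modules)), function(m) {
    idx <- which(modules == m)
    if (length(idx) < 2L) return(NA_real_)
    mean(r[idx, idx], na.rm = TRUE)
  }, numeric(1))
  list(within = within, between = between, perModule = perModule)
}
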