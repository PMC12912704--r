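#' Build the shared/unique gene mask from a reference and an ST matrix
#'
#' A gene is "shared" when its name occurs in both the reference and the ST
#' matrix; shared genes carry the conditioning signal and unique genes are
#' the imputation targets. Matching is exact and case-sensitive by default
#' because silent case-folding invites cross-species identifier accidents.
#'
#' @param reference [ExpressionMatrix-class], the scRNA-seq reference.
#' @param st [ExpressionMatrix-class], the spatial matrix.
#' @param nCells number of rows the mask should have (defaults to the
#'   reference cell count; at training time the mask is subset per batch).
#' @param caseFold if `TRUE`, match gene names case-insensitively.
#' @return A [GeneMask-class] over the reference gene axis.
#' @export
buildGeneMask <- function(reference, st, nCells = nrow(reference@values),
                          caseFold = FALSE) {
  stopifnot(is(reference, "ExpressionMatrix"), is(st, "ExpressionMatrix"))
  gref <- reference@geneNames
  gst <- st@geneNames
  hit <- if (caseFold) tolower(gref) %in% tolower(gst) else gref %in% gst
  shared <- gref[hit]
  if (!length(shared)) {
    stop("no shared genes between reference and ST matrix; imputation is impossible")
  }
  col <- as.numeric(hit)
  m <- matrix(rep(col, each = nCells), nrow = nCells,
              dimnames = list(NULL, gref))
  new("GeneMask", m = m, sharedGenes = shared, geneNames = gref)
}

# Subset or re-broadcast a GeneMask to a given number of cells.
maskForCells <- function(mask, nCells) {
  col <- as.numeric(mask@geneNames %in% mask@sharedGenes)
  matrix(rep(col, each = nCells), nrow = nCells,
         dimnames = list(NULL, mask@geneNames))
}

# A GeneMask with some shared genes re-labelled unique (fold holdout).
dropSharedGenes <- function(mask, heldOut) {
  stopifnot(all(heldOut %in% mask@sharedGenes))
  shared <- setdiff(mask@sharedGenes, heldOut)
  if (!length(shared)) stop("holding out all shared genes leaves no conditioning signal")
  col <- as.numeric(mask@geneNames %in% shared)
  m <- matrix(rep(col, each = nrow(mask@m)), nrow = nrow(mask@m),
              dimnames = list(NULL, mask@geneNames))
  new("GeneMask", m = m, sharedGenes = mask@geneNames[col == 1],
      geneNames = mask@geneNames)
}

#' Deterministic k-fold split of the shared genes
#'
#' Shared genes are shuffled once under `seed` and dealt into `k` folds whose
#' sizes differ by at most one. During fold i the assigned genes are treated
#' as unique (held out of the ST conditional) and scored against their
#' measured values.
#'
#' @param mask a [GeneMask-class].
#' @param k fold count (default 5).
#' @param seed integer seed; the same call always returns the same plan.
#' @return A [SplitPlan-class].
#' @export
makeCVSplits <- function(mask, k = 5L, seed = 0L) {
  stopifnot(is(mask, "GeneMask"))
  k <- as.integer(k)
  genes <- mask@sharedGenes
  if (k < 2L) stop("k must be >= 2")
  if (k > length(genes)) {
    stop(sprintf("k = %d exceeds the number of shared genes (%d)",
                 k, length(genes)))
  }
  perm <- withSeed(seed, sample.int(length(genes)))
  folds <- integer(length(genes))
  folds[perm] <- (seq_along(genes) - 1L) %% k
  names(folds) <- genes
  new("SplitPlan", foldAssignments = folds, k = k)
}

#' Normalize expression values
#'
#' `"lognorm"` library-size normalizes every cell to `targetSum` total counts
#' and applies `log1p`; `"raw"` returns the input untouched (use it when the
#' matrices are already on a normalized log-like scale, as the synthetic
#' generator's output is). Both modalities must be passed through the same
#' setting before training or imputation.
#'
#' @param x an [ExpressionMatrix-class].
#' @param method `"lognorm"` (default) or `"raw"`.
#' @param targetSum per-cell total after library-size scaling.
#' @return An [ExpressionMatrix-class] on the chosen scale.
#' @export
normalizeExpression <- function(x, method = c("lognorm", "raw"),
                                targetSum = 1e4) {
  method <- match.arg(method)
  stopifnot(is(x, "ExpressionMatrix"))
  if (method == "raw") return(x)
  v <- x@values
  libs <- rowSums(v)
  libs[libs == 0] <- 1
  v <- log1p(v / libs * targetSum)
  ExpressionMatrix(v, x@geneNames, x@cellNames, x@modality)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Named RNG substreams fanned out from one master seed so that, e.g., the
# sampler stream is unaffected by how many perturbation draws were consumed.
subSeed <- function(seed, stream) {
  offsets <- c(perturb = 1L, timestep = 2L, noise = 3L, sampler = 4L,
               folds = 5L, clustering = 6L, init = 7L, batch = 8L,
               simulate = 9L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 131L + offsets[[stream]] * 10007) %% 2147483647)
}
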