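# Gene-level similarity metrics, clustering agreement metrics, and the
# rank-aggregate accuracy score. Gene-level metrics take a predicted and a
# measured expression vector over the same cells; clustering metrics compare
# two labelings through their contingency table (natural logarithms
# throughout).

#' Spearman rank correlation of one gene (SPCC)
#'
#' For tie-free data uses the classical rank-difference form
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))`; with ties it falls back to Pearson
#' correlation of the average ranks (the rank-difference form is exact only
#' without ties).
#'
#' @param pred,truth numeric vectors of equal length (n >= 2).
#' @return Correlation in `[-1, 1]`; `NaN` with a warning if either vector is
#'   constant.
#' @export
spccGene <- function(pred, truth) {
  n <- length(pred)
  if (n < 2L || length(truth) != n) stop("need two equal-length vectors, n >= 2")
  if (stats::var(pred) == 0 || stats::var(truth) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NaN)
  }
  rp <- rank(pred); rt <- rank(truth)
  if (anyDuplicated(pred) || anyDuplicated(truth)) {
    return(stats::cor(rp, rt))
  }
  d <- rp - rt
  1 - 6 * sum(d * d) / (n * (n^2 - 1))
}

#' Structural similarity of one gene (SSIM)
#'
#' Both vectors are min-max scaled to `[0, 1]` per gene, then
#' `(2 mu_T mu_P + C1^2)(2 cov + C2^2) / ((mu_T^2 + mu_P^2 + C1^2)
#' (var_T + var_P + C2^2))` is evaluated with `C1 = 0.01`, `C2 = 0.03`
#' (sample covariance/variance). Symmetric in its arguments.
#'
#' @param pred,truth numeric vectors of equal length (n >= 2).
#' @param c1,c2 stabilizing constants on the unit range.
#' @return SSIM value (1 for identical vectors).
#' @export
ssimGene <- function(pred, truth, c1 = 0.01, c2 = 0.03) {
  n <- length(pred)
  if (n < 2L || length(truth) != n) stop("need two equal-length vectors, n >= 2")
  mm <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x
  }
  p <- mm(pred); t <- mm(truth)
  mp <- mean(p); mt <- mean(t)
  vp <- stats::var(p); vt <- stats::var(t)
  cv <- stats::cov(t, p)
  (2 * mt * mp + c1^2) * (2 * cv + c2^2) /
    ((mt^2 + mp^2 + c1^2) * (vt + vp + c2^2))
}

#' Root mean square error of one gene on z-scores
#'
#' Both vectors are z-scored per gene before the RMSE, making the measure
#' invariant to simultaneous affine rescaling. If either vector has zero
#' variance, z-scores are undefined and the function falls back to raw-scale
#' RMSE with a warning; `scale = "raw"` requests raw-scale RMSE directly.
#'
#' @param pred,truth numeric vectors of equal length.
#' @param scale `"zscore"` (default) or `"raw"`.
#' @return RMSE (0 for identical vectors).
#' @export
rmseGene <- function(pred, truth, scale = c("zscore", "raw")) {
  scale <- match.arg(scale)
  if (length(pred) != length(truth)) stop("length mismatch")
  if (scale == "zscore") {
    if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
      if (!isTRUE(all.equal(pred, truth))) {
        warning("zero-variance vector: falling back to raw-scale RMSE")
      }
      return(sqrt(mean((pred - truth)^2)))
    }
    pred <- (pred - mean(pred)) / stats::sd(pred)
    truth <- (truth - mean(truth)) / stats::sd(truth)
  }
  sqrt(mean((pred - truth)^2))
}

#' Jensen-Shannon divergence of one gene
#'
#' Each nonnegative vector is normalized to a probability distribution over
#' cells; the JS divergence is the mean of the two KL divergences against the
#' mixture, with natural logarithms and the `0 * log 0 = 0` convention.
#' Bounded in `[0, ln 2]` and symmetric.
#'
#' @param pred,truth nonnegative vectors of equal length with positive sums.
#' @return JS divergence; 0 when the vectors are proportional, `ln 2` for
#'   disjoint support.
#' @export
jsGene <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (any(pred < 0) || any(truth < 0)) stop("vectors must be nonnegative")
  if (sum(pred) <= 0 || sum(truth) <= 0) stop("zero-sum vector")
  p <- pred / sum(pred)
  q <- truth / sum(truth)
  m <- (p + q) / 2
  klTo <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (klTo(p) + klTo(q)) / 2
}

# ---- clustering agreement ------------------------------------------------

contingency <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, adjusted for chance via the
#' hypergeometric expectation; 1 for identical labelings (up to relabeling),
#' about 0 for independent ones.
#'
#' @param predLabels,trueLabels equal-length labelings.
#' @return ARI (at most 1).
#' @export
ariScore <- function(predLabels, trueLabels) {
  N <- contingency(predLabels, trueLabels)
  n <- sum(N)
  sij <- sum(choose(N, 2))
  sa <- sum(choose(rowSums(N), 2))
  sb <- sum(choose(colSums(N), 2))
  expIdx <- sa * sb / choose(n, 2)
  maxIdx <- (sa + sb) / 2
  if (maxIdx == expIdx) return(1)  # both labelings trivial
  (sij - expIdx) / (maxIdx - expIdx)
}

entropyFromCounts <- function(cnt) {
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

mutualInfo <- function(N) {
  n <- sum(N)
  pij <- N / n
  pi <- rowSums(pij); pj <- colSums(pij)
  i <- which(pij > 0, arr.ind = TRUE)
  sum(pij[i] * log(pij[i] / (pi[i[, 1]] * pj[i[, 2]])))
}

#' Normalized mutual information
#'
#' `MI / sqrt(H(P) * H(T))` — geometric-mean normalization.
#'
#' @inheritParams ariScore
#' @return NMI in `[0, 1]`.
#' @export
nmiScore <- function(predLabels, trueLabels) {
  N <- contingency(predLabels, trueLabels)
  hp <- entropyFromCounts(rowSums(N))
  ht <- entropyFromCounts(colSums(N))
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) {
    warning("single-cluster labeling: NMI undefined, returning 0")
    return(0)
  }
  mutualInfo(N) / sqrt(hp * ht)
}

# Expected mutual information under the permutation (hypergeometric) model.
expectedMI <- function(N) {
  n <- sum(N)
  a <- rowSums(N); b <- colSums(N)
  a <- unname(a); b <- unname(b)
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(a[i] + b[j] - n, 1)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        term <- nij / n * log(n * nij / (a[i] * b[j]))
        lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) + lgamma(n - a[i] + 1) +
          lgamma(n - b[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
          lgamma(n - a[i] - b[j] + nij + 1)
        emi <- emi + term * exp(lp)
      }
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' `(MI - E[MI]) / (avg(H(P), H(T)) - E[MI])` with the expected MI computed
#' under the permutation model and arithmetic-mean normalization; about 0 for
#' independent labelings, 1 for identical ones.
#'
#' @inheritParams ariScore
#' @return AMI (at most 1).
#' @export
amiScore <- function(predLabels, trueLabels) {
  N <- contingency(predLabels, trueLabels)
  hp <- entropyFromCounts(rowSums(N))
  ht <- entropyFromCounts(colSums(N))
  if (hp == 0 && ht == 0) return(1)
  mi <- mutualInfo(N)
  emi <- expectedMI(N)
  den <- (hp + ht) / 2 - emi
  if (abs(den) < 1e-15) {
    warning("degenerate labelings: AMI denominator is zero, returning 0")
    return(0)
  }
  (mi - emi) / den
}

#' Homogeneity
#'
#' `1 - H(T | P) / H(T)`: 1 when every predicted cluster contains members of
#' a single true class.
#'
#' @inheritParams ariScore
#' @return Homogeneity in `[0, 1]`; if the true labeling has a single class
#'   the measure is undefined and 1 is returned with a warning.
#' @export
homoScore <- function(predLabels, trueLabels) {
  N <- contingency(predLabels, trueLabels)
  ht <- entropyFromCounts(colSums(N))
  if (ht == 0) {
    warning("single-cluster truth: homogeneity undefined, returning 1 by convention")
    return(1)
  }
  hJoint <- entropyFromCounts(as.vector(N))
  hp <- entropyFromCounts(rowSums(N))
  hTgivenP <- hJoint - hp
  1 - hTgivenP / ht
}

#' Leiden clustering of an expression matrix
#'
#' The standard graph-clustering harness: PCA (up to `nPCs` components), a
#' symmetrized k-nearest-neighbour graph, and Leiden community detection at
#' the given resolution (modularity objective). Deterministic given `seed`.
#'
#' @param x [ExpressionMatrix-class] or numeric matrix (cells x genes).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed integer seed.
#' @param nPCs number of principal components (default 50, capped by the
#'   data).
#' @param kNN neighbours per cell (default 15; reduced with a warning when
#'   there are too few cells).
#' @return Integer cluster labels, one per cell.
#' @export
clusterCells <- function(x, resolution = 1, seed = 0L, nPCs = 50L, kNN = 15L) {
  v <- if (is(x, "ExpressionMatrix")) x@values else x
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 cells to cluster")
  if (kNN >= n) {
    warning(sprintf("kNN reduced from %d to %d (too few cells)", kNN, n - 1L))
    kNN <- n - 1L
  }
  nPCs <- min(nPCs, n - 1L, ncol(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = nPCs)$x
  d <- as.matrix(stats::dist(pc))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(kNN)]
    cbind(i, nb)
  }))
  gph <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gph <- igraph::simplify(gph)
  memb <- withSeed(subSeed(seed, "clustering"),
                   igraph::cluster_leiden(gph, objective_function = "modularity",
                                          resolution = resolution,
                                          n_iterations = 5L)$membership)
  as.integer(memb)
}

#' Rank-aggregate accuracy score (AS)
#'
#' Within every (dataset, metric) cell the methods are ranked so that better
#' performance receives the higher rank (lower-is-better metrics are
#' reversed; ties get average ranks). A method's AS is its mean rank across
#' all cells — higher is better.
#'
#' @param results 3-D numeric array `method x dataset x metric` with
#'   dimnames. Missing cells receive the mean rank `(M + 1) / 2` with a
#'   warning.
#' @param orientation named character vector over metrics, each `"higher"` or
#'   `"lower"` (is better).
#' @return A data.frame with columns `method` and `AS`, plus the full rank
#'   array in `attr(, "ranks")`.
#' @export
asScore <- function(results, orientation) {
  stopifnot(length(dim(results)) == 3L)
  metrics <- dimnames(results)[[3]]
  if (!all(metrics %in% names(orientation))) {
    stop("orientation must name every metric")
  }
  M <- dim(results)[1]
  ranks <- results * NA
  for (ds in seq_len(dim(results)[2])) {
    for (mt in seq_len(dim(results)[3])) {
      v <- results[, ds, mt]
      if (anyNA(v)) {
        warning("missing cells receive the mean rank")
      }
      r <- if (orientation[[metrics[mt]]] == "higher") rank(v, na.last = "keep")
           else rank(-v, na.last = "keep")
      r[is.na(r)] <- (M + 1) / 2
      ranks[, ds, mt] <- r
    }
  }
  as <- apply(ranks, 1, mean)
  structure(data.frame(method = dimnames(results)[[1]], AS = as,
                       row.names = NULL),
            ranks = ranks)
}
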