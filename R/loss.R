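#' Masked training loss: MSE plus KL regularization
#'
#' The loss is computed only over the masked (unique-gene, mask value 0)
#' entries, where the model actually has to predict noise:
#' `total = MSE(eps*(1-m), epsHat*(1-m)) + alpha * KL`. The KL term pulls the
#' distribution of the predicted masked noise toward the standard-normal
#' target; by default it is the closed-form Gaussian divergence after moment
#' matching — fit `(mu, sigma)` to the masked entries of `epsHat` and
#' evaluate `KL(N(mu, sigma^2) || N(0,1))`. An empirical-histogram estimate
#' is available via `klMethod = "histogram"` (evaluation only; training uses
#' the differentiable Gaussian form).
#'
#' @param eps true noise matrix.
#' @param epsHat predicted noise matrix, same shape.
#' @param m binary mask matrix (or [GeneMask-class]); 1 = shared gene
#'   (excluded from the loss), 0 = unique gene.
#' @param alpha KL weight (>= 0).
#' @param klMethod `"gaussian"` (default) or `"histogram"`.
#' @return A `LossBreakdown` list: `mse`, `kl`, `total = mse + alpha * kl`.
#' @export
trainingLoss <- function(eps, epsHat, m, alpha, klMethod = c("gaussian", "histogram")) {
  klMethod <- match.arg(klMethod)
  if (is(m, "GeneMask")) m <- maskForCells(m, nrow(eps))
  if (!identical(dim(eps), dim(epsHat)) || !identical(dim(eps), dim(m))) {
    stop("shape mismatch")
  }
  if (alpha < 0) stop("alpha must be >= 0")
  masked <- m == 0
  if (!any(masked)) stop("no masked (unique-gene) entries to compute the loss on")
  d <- epsHat[masked] - eps[masked]
  mse <- mean(d * d)
  z <- epsHat[masked]
  kl <- if (klMethod == "gaussian") {
    mu <- mean(z)
    s2 <- max(mean((z - mu)^2), 1e-12)
    -0.5 * log(s2) + (s2 + mu * mu - 1) / 2
  } else {
    br <- seq(min(z, -4) - 1e-9, max(z, 4) + 1e-9, length.out = 41L)
    p <- tabulate(findInterval(z, br, rightmost.closed = TRUE),
                  nbins = 40L) / length(z)
    q <- diff(stats::pnorm(br))
    keep <- p > 0
    sum(p[keep] * log(p[keep] / pmax(q[keep], 1e-12)))
  }
  structure(list(mse = mse, kl = kl, total = mse + alpha * kl),
            class = "LossBreakdown")
}

# Gradient of the Gaussian-KL training loss w.r.t. epsHat. Exactly zero at
# shared-gene entries: both terms only touch masked entries.
lossGrad <- function(eps, epsHat, m, alpha) {
  if (is(m, "GeneMask")) m <- maskForCells(m, nrow(eps))
  masked <- m == 0
  nMask <- sum(masked)
  d <- matrix(0, nrow(eps), ncol(eps))
  z <- epsHat[masked]
  mu <- mean(z)
  s2 <- max(mean((z - mu)^2), 1e-12)
  dm <- 2 * (epsHat[masked] - eps[masked]) / nMask
  dk <- mu / nMask + (1 - 1 / s2) * (z - mu) / nMask
  d[masked] <- dm + alpha * dk
  d
}
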