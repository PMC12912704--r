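#' Cosine noise schedule
#'
#' Builds the cumulative retention curve `gamma[t] = f(t)/f(0)` with
#' `f(u) = cos^2((u/T + offset)/(1 + offset) * pi/2)` and per-step factors
#' `alpha[t] = gamma[t]/gamma[t-1]`, clipped into `(1e-6, 0.9999)` with gamma
#' recomputed as the cumulative product of the clipped alphas so the class
#' invariant `gamma == cumprod(alpha)` holds exactly.
#'
#' @param T number of diffusion steps (>= 1).
#' @param offset small offset keeping `alpha[1]` below 1 (default 0.008).
#' @return A [NoiseSchedule-class].
#' @examples
#' s <- buildCosineSchedule(1000)
#' s@gamma[1]; s@gamma[1000]
#' @export
buildCosineSchedule <- function(T, offset = 0.008) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be >= 1")
  f <- function(u) cos(((u / T + offset) / (1 + offset)) * pi / 2)^2
  gam <- f(seq_len(T)) / f(0)
  alpha <- gam / c(1, gam[-T])
  alpha <- pmin(pmax(alpha, 1e-6), 0.9999)
  gam <- cumprod(alpha)
  new("NoiseSchedule", T = T, alpha = alpha, gamma = gam, offset = offset)
}

#' Forward diffusion step
#'
#' Corrupts clean data to noise level t:
#' `x_t = sqrt(gamma[t]) * x0 + sqrt(1 - gamma[t]) * eps`. This is
#' variance-preserving: for unit-variance `x0` and standard-normal `eps`,
#' `x_t` keeps unit variance at every t.
#'
#' @param x0 clean matrix (cells x genes).
#' @param t timestep in `1..T`.
#' @param eps noise matrix of the same shape as `x0`.
#' @param s a [NoiseSchedule-class].
#' @return The corrupted matrix, same shape as `x0`.
#' @export
forwardDiffuse <- function(x0, t, eps, s) {
  if (!identical(dim(x0), dim(eps))) stop("x0 and eps shapes differ")
  t <- as.integer(t)
  if (t < 1L || t > s@T) stop("t out of schedule range")
  g <- s@gamma[t]
  sqrt(g) * x0 + sqrt(1 - g) * eps
}

#' Compose the masked network input
#'
#' Splices two matrices by the shared/unique gene mask:
#' `x0_like * m + xt * (1 - m)` — shared-gene entries come from the clean
#' (or conditional) matrix, unique-gene entries from the diffused state.
#'
#' @param x0Like matrix supplying the shared-gene entries.
#' @param xt matrix supplying the unique-gene entries.
#' @param m binary mask matrix of the same shape (or a [GeneMask-class],
#'   re-broadcast to the row count of `xt`).
#' @return The composed matrix.
#' @export
composeMaskedInput <- function(x0Like, xt, m) {
  if (is(m, "GeneMask")) m <- maskForCells(m, nrow(xt))
  if (!identical(dim(x0Like), dim(xt)) || !identical(dim(xt), dim(m))) {
    stop("shape mismatch between inputs and mask")
  }
  x0Like * m + xt * (1 - m)
}

#' Reverse (denoising) step
#'
#' One step of ancestral sampling from the learned reverse chain:
#' `x_{t-1} = (x_t - (1 - alpha[t]) / sqrt(1 - gamma[t]) * epsHat) /
#' sqrt(alpha[t]) + sqrt(1 - alpha[t]) * epsT`. Fresh noise `epsT` is added
#' for t > 1 and must be zero at t = 1 (the final, deterministic step). At
#' t = 1, where `gamma[1] = alpha[1]`, feeding back the true forward noise
#' inverts [forwardDiffuse()] exactly.
#'
#' @param xt current state (cells x genes).
#' @param epsHat predicted noise, same shape.
#' @param t timestep in `1..T`.
#' @param s a [NoiseSchedule-class].
#' @param epsT fresh standard-normal noise matrix, or 0 at t = 1.
#' @return The state at t - 1.
#' @export
reverseStep <- function(xt, epsHat, t, s, epsT = 0) {
  t <- as.integer(t)
  if (t < 1L || t > s@T) stop("t out of schedule range")
  if (!identical(dim(xt), dim(epsHat))) stop("xt and epsHat shapes differ")
  a <- s@alpha[t]
  g <- s@gamma[t]
  (xt - (1 - a) / sqrt(1 - g) * epsHat) / sqrt(a) + sqrt(1 - a) * epsT
}

#' Perturb the reference with stochastic noise
#'
#' Training-time augmentation: adds i.i.d. Gaussian noise to the reference so
#' the model keys on gene-gene relationships rather than absolute values,
#' buffering the batch discrepancy between modalities.
#'
#' @param x0 an [ExpressionMatrix-class] or plain matrix.
#' @param sd noise standard deviation (>= 0; 0 returns the input).
#' @param seed integer seed; deterministic given it.
#' @return A plain matrix `x0 + N(0, sd^2)` (not clipped; downstream code
#'   works on the standardized scale).
#' @export
perturbReference <- function(x0, sd = 0.1, seed = 0L) {
  v <- if (is(x0, "ExpressionMatrix")) x0@values else x0
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(v)
  v + withSeed(seed, matrix(stats::rnorm(length(v), 0, sd), nrow(v), ncol(v)))
}
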