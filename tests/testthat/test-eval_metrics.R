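# Independent brute-force oracles, written from the definitions rather than
# the implementation under test.

pairCountARI <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sameA <- a[i] == a[j]; sameB <- b[i] == b[j]
    if (sameA && sameB) ss <- ss + 1
    else if (sameA && !sameB) sd <- sd + 1
    else if (!sameA && sameB) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- choose(n, 2)
  sumA <- ss + sd; sumB <- ss + ds
  exp0 <- sumA * sumB / tot
  (ss - exp0) / ((sumA + sumB) / 2 - exp0)
}

directMI <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    pij <- sum(a == u & b == v) / n
    if (pij > 0) mi <- mi + pij * log(pij / (sum(a == u) / n * sum(b == v) / n))
  }
  mi
}

directH <- function(a) {
  p <- table(a) / length(a)
  -sum(p * log(p))
}

# exact expected MI by enumerating every permutation of one labeling
permutationEMI <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  mean(vapply(perms(a), function(ap) directMI(ap, b), numeric(1)))
}

test_that("SPCC hits its closed forms and the rank-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spccGene(x, x), 1, tolerance = 1e-12)
  expect_equal(spccGene(x, -x), -1, tolerance = 1e-12)
  withr::with_seed(1, {
    p <- rnorm(5); t <- rnorm(5)
  })
  expect_lt(abs(spccGene(p, t) - cor(rank(p), rank(t))), 1e-12)
  expect_lt(abs(spccGene(p, t) - cor(p, t, method = "spearman")), 1e-12)
  # ties fall back to Pearson-on-average-ranks
  pt <- c(1, 1, 2, 3); tt <- c(4, 2, 2, 1)
  expect_equal(spccGene(pt, tt), cor(rank(pt), rank(tt)), tolerance = 1e-12)
  expect_warning(res <- spccGene(rep(1, 4), 1:4), "constant")
  expect_true(is.nan(res))
})

test_that("SSIM is 1 at identity, small for mismatched constants, symmetric", {
  withr::with_seed(2, x <- runif(20))
  expect_equal(ssimGene(x, x), 1, tolerance = 1e-6)
  expect_lt(ssimGene(rep(0, 10), rep(1, 10)), 0.1)
  withr::with_seed(3, y <- runif(20))
  expect_equal(ssimGene(x, y), ssimGene(y, x), tolerance = 1e-12)
  # independent scalar evaluation of the formula
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  p <- mm(x); t <- mm(y)
  want <- (2 * mean(t) * mean(p) + 0.01^2) * (2 * cov(t, p) + 0.03^2) /
    ((mean(t)^2 + mean(p)^2 + 0.01^2) * (var(t) + var(p) + 0.03^2))
  expect_lt(abs(ssimGene(x, y) - want), 1e-12)
})

test_that("RMSE is on z-scores and affine invariant", {
  x <- c(1, 2, 3); y <- c(2, 2.5, 4)
  zx <- (x - mean(x)) / sd(x); zy <- (y - mean(y)) / sd(y)
  expect_lt(abs(rmseGene(x, y) - sqrt(mean((zx - zy)^2))), 1e-12)
  expect_equal(rmseGene(x, x), 0)
  expect_equal(rmseGene(10 * x + 3, 10 * y + 3), rmseGene(x, y),
               tolerance = 1e-12)
  expect_warning(rmseGene(rep(1, 3), c(1, 2, 3)), "zero-variance")
  expect_equal(rmseGene(x, y, scale = "raw"), sqrt(mean((x - y)^2)),
               tolerance = 1e-12)
})

test_that("JS divergence: boundaries exact, term-summation oracle matches", {
  expect_equal(jsGene(c(2, 4, 6), c(1, 2, 3)), 0, tolerance = 1e-14)
  expect_equal(jsGene(c(1, 0), c(0, 1)), log(2), tolerance = 1e-14)
  withr::with_seed(4, {
    a <- rexp(6); b <- rexp(6)
  })
  p <- a / sum(a); q <- b / sum(b); m <- (p + q) / 2
  want <- 0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))
  expect_lt(abs(jsGene(a, b) - want), 1e-12)
  expect_equal(jsGene(a, b), jsGene(b, a), tolerance = 1e-14)
  expect_true(jsGene(a, b) >= 0 && jsGene(a, b) <= log(2))
  expect_error(jsGene(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(jsGene(c(0, 0), c(1, 1)), "zero-sum")
})

test_that("ARI matches brute-force pair counting and mclust", {
  a <- c(1, 1, 2, 2, 2, 3)
  b <- c(2, 2, 2, 3, 3, 1)
  expect_lt(abs(ariScore(a, b) - pairCountARI(a, b)), 1e-12)
  skip_if_not_installed("mclust")
  expect_lt(abs(ariScore(a, b) - mclust::adjustedRandIndex(a, b)), 1e-12)
  expect_equal(ariScore(a, a), 1)
  # permutation invariance of label ids
  expect_equal(ariScore(a, c(9, 9, 7, 7, 7, 5)), 1)
})

test_that("NMI / AMI / Homo match direct entropy summation on a toy table", {
  a <- c(1, 1, 1, 2, 2, 3, 3, 3)
  b <- c(1, 1, 2, 2, 2, 3, 3, 1)
  mi <- directMI(a, b)
  expect_lt(abs(nmiScore(a, b) - mi / sqrt(directH(a) * directH(b))), 1e-10)
  hcond <- directH(paste(a, b)) - directH(a)
  expect_lt(abs(homoScore(a, b) - (1 - hcond / directH(b))), 1e-10)
  emi <- permutationEMI(a, b)
  want <- (mi - emi) / ((directH(a) + directH(b)) / 2 - emi)
  expect_lt(abs(amiScore(a, b) - want), 1e-8)
  # identical labelings
  expect_equal(nmiScore(a, a), 1, tolerance = 1e-12)
  expect_equal(amiScore(a, a), 1, tolerance = 1e-12)
  expect_equal(homoScore(a, a), 1, tolerance = 1e-12)
  expect_warning(h1 <- homoScore(a, rep(1, 8)), "convention")
  expect_identical(h1, 1)
})

test_that("independent labelings give AMI near zero and NMI above AMI", {
  withr::with_seed(5, {
    a <- sample(1:5, 1000, replace = TRUE)
    b <- sample(1:5, 1000, replace = TRUE)
  })
  ami <- amiScore(a, b)
  expect_lt(abs(ami), 0.05)
  expect_gt(nmiScore(a, b), ami)
})

test_that("Leiden harness recovers well-separated blobs deterministically", {
  withr::with_seed(6, {
    n <- 60
    x <- rbind(matrix(rnorm(n * 10, 0, 0.3), n, 10),
               matrix(rnorm(n * 10, 4, 0.3), n, 10))
  })
  truth <- rep(1:2, each = n)
  lab <- clusterCells(x, resolution = 1, seed = 1)
  expect_gt(ariScore(lab, truth), 0.9)
  expect_identical(lab, clusterCells(x, resolution = 1, seed = 1))
  # higher resolution never yields fewer clusters on this data
  ks <- vapply(c(0.2, 1, 4),
               function(r) length(unique(clusterCells(x, r, seed = 1))),
               numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_warning(clusterCells(x[1:5, ], kNN = 15), "reduced")
})

test_that("AS ranks methods per cell with the right orientation", {
  res <- array(NA_real_, c(2, 2, 2),
               dimnames = list(c("A", "B"), c("d1", "d2"), c("spcc", "rmse")))
  res["A", , "spcc"] <- c(0.9, 0.8); res["B", , "spcc"] <- c(0.5, 0.4)
  res["A", , "rmse"] <- c(0.1, 0.2); res["B", , "rmse"] <- c(0.9, 0.8)
  out <- asScore(res, c(spcc = "higher", rmse = "lower"))
  expect_equal(out$AS[out$method == "A"], 2)
  expect_equal(out$AS[out$method == "B"], 1)
  # a single method gets rank 1 everywhere
  res1 <- res[1, , , drop = FALSE]
  expect_equal(asScore(res1, c(spcc = "higher", rmse = "lower"))$AS, 1)
  # duplicated methods tie at the average rank
  res2 <- res; res2["B", , ] <- res2["A", , ]
  out2 <- asScore(res2, c(spcc = "higher", rmse = "lower"))
  expect_equal(out2$AS, c(1.5, 1.5))
  # 3-method enumeration oracle
  res3 <- array(c(3, 1, 2, 1, 2, 3,   # d1/d2 for metric m (higher better)
                  2, 3, 1, 3, 2, 1),  # d1/d2 for metric r (lower better)
                c(3, 2, 2),
                dimnames = list(c("A", "B", "C"), c("d1", "d2"), c("m", "r")))
  out3 <- asScore(res3, c(m = "higher", r = "lower"))
  # hand ranks: m/d1: A=3,B=1,C=2; m/d2: A=1,B=2,C=3;
  #             r/d1 (reversed): A=2,B=1,C=3; r/d2: A=1,B=2,C=3
  expect_equal(out3$AS, c((3 + 1 + 2 + 1) / 4, (1 + 2 + 1 + 2) / 4,
                          (2 + 3 + 3 + 3) / 4))
})
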