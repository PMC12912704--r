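# AdamW (decoupled weight decay) over arbitrarily nested parameter trees.
# Parameter and gradient trees share their structure; moment trees are
# initialized lazily to zeros.

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), step = 0L)
}

adamUpdate <- function(params, grads, state, lr, weightDecay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      # unnamed lists (e.g. block/layer sequences)
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          if (is.null(g[[i]])) next
          r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
          out$p[[i]] <- r$p; out$m[[i]] <- r$m; out$v[[i]] <- r$v
        }
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weightDecay * p)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, step = state$step))
}
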