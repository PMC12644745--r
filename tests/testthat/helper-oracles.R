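# Independent oracles used to freeze expected values.

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (average ranks, so valid under ties).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- drop(signs %*% r)
  min(1, 2 * min(mean(W <= obs + 1e-9), mean(W >= obs - 1e-9)))
}

# Benjamini-Hochberg step-up written from its definition.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Exhaustive tuned-model fit: per candidate, nonnegative amplitude and free
# baseline by direct least squares on the explicit prediction.
brute_force_tuned <- function(y, grid, basis, m) {
  levels <- as.numeric(colnames(basis))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- exp(-(log(levels) - grid$pref_log[i])^2 / (2 * grid$width_log[i]^2))
    p <- m * drop(basis %*% g)
    pc <- p - mean(p); yc <- y - mean(y)
    a <- if (sum(pc^2) > 0) max(0, sum(pc * yc) / sum(pc^2)) else 0
    sse <- sum((yc - a * pc)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(i = i, sse = sse, amplitude = a)
  }
  best
}
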