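# Shared fixtures and independent oracles used across the test files.

# small deterministic connectome with hand-set weights
toy_connectome <- function(A, extent = 60) {
  n <- nrow(A)
  set.seed(42)
  centroids <- matrix(runif(n * 3, -extent / 2, extent / 2), n, 3)
  connectome(A, paste0("V", seq_len(n)), centroids, rep(1000, n))
}

# two disconnected weighted cliques of size k each
two_block_connectome <- function(k = 5, w = 10) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- w
  A[(k + 1):n, (k + 1):n] <- w
  diag(A) <- 0
  toy_connectome(A)
}

# brute-force maximum-lag Pearson FC oracle (R loop over every lag)
fc_brute <- function(X, max_lag) {
  n <- ncol(X); T <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in i:n) {
    if (sd(X[, i]) == 0 || sd(X[, j]) == 0) next
    best <- -Inf
    for (lag in -max_lag:max_lag) {
      t0 <- max(1, 1 - lag); t1 <- min(T, T - lag)
      if (t1 - t0 + 1 < 3) next
      xi <- X[t0:t1, i]; yj <- X[(t0 + lag):(t1 + lag), j]
      if (sd(xi) == 0 || sd(yj) == 0) next
      best <- max(best, min(1, max(-1, cor(xi, yj))))
    }
    out[i, j] <- out[j, i] <- if (is.finite(best)) best else NA_real_
  }
  diag(out) <- ifelse(apply(X, 2, sd) == 0, NA_real_, 1)
  out
}

# brute-force Benjamini-Hochberg step-up with monotonicity enforcement
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# scalar single-region Wilson-Cowan drift, written independently of the
# package's vectorized implementation
wc_drift_scalar <- function(E, I, params, P = 0) {
  p <- params
  S <- function(x, a, th) 1 / (1 + exp(-a * (x - th))) - 1 / (1 + exp(a * th))
  c(dE = (-E + (p$S_E_max - E) * S(p$c1 * E - p$c2 * I + P, p$a_E, p$theta_E)) / p$tau,
    dI = (-I + (p$S_I_max - I) * S(p$c3 * E - p$c4 * I, p$a_I, p$theta_I)) / p$tau)
}
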