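# Independent oracles used across the suite. These deliberately use naive,
# dense, loop-based formulations so they share no code path with the package.

# random PSD covariance with distinct positive variances
rand_psd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  crossprod(A) / (p + 2) + diag(seq_len(p)) * 0.5
}

# symmetric matrix power via eigendecomposition (duplicate of nothing in R/)
oracle_mpow <- function(M, pow) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals^pow * t(e$vectors))
}

# double-loop shrinkage intensity from centered cross-product deviations
oracle_intensity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xs <- scale(x)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- xs[, i] * xs[, j]
      r_ij <- n / (n - 1) * mean(w)
      v_ij <- n / (n - 1)^3 * sum((w - mean(w))^2)
      num <- num + 2 * v_ij
      den <- den + 2 * r_ij^2
    }
  }
  if (den == 0) return(1)
  min(1, max(0, num / den))
}

# dense shrunk correlation matrix
oracle_shrink_cor <- function(x, lambda) {
  lambda * diag(ncol(x)) + (1 - lambda) * cor(x)
}

# classical CCA magnitudes from the generalized eigenproblem
oracle_classical_cca <- function(X, Y) {
  m <- min(ncol(X), ncol(Y))
  M <- solve(cov(X)) %*% cov(X, Y) %*% solve(cov(Y)) %*% cov(Y, X)
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)[seq_len(m)]
  sqrt(pmax(ev, 0))
}

# K matrix built from dense eigen-based inverse square roots
oracle_K <- function(P_X, P_XY, P_Y) {
  oracle_mpow(P_X, -1/2) %*% P_XY %*% oracle_mpow(P_Y, -1/2)
}

# toy CSV fixture written on the fly
write_toy_table <- function(path, ids, values, sep = ",") {
  df <- data.frame(sample_id = ids, values, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
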