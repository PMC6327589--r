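#' Analytic shrinkage intensity for a correlation matrix
#'
#' Estimates the variance-minimizing weight \eqn{\lambda} for shrinking the
#' empirical correlation matrix toward the identity,
#' \deqn{\lambda^{*} = \frac{\sum_{i \ne j} \widehat{\mathrm{var}}(r_{ij})}
#'                          {\sum_{i \ne j} r_{ij}^2},}
#' clipped into \eqn{[0, 1]}. The variance of each empirical correlation is
#' estimated from the centered cross-products of the standardized data
#' (\eqn{w_{kij} = x^{s}_{ki} x^{s}_{kj}}):
#' \eqn{\widehat{\mathrm{var}}(r_{ij}) = \frac{n}{(n-1)^3}
#' \sum_k (w_{kij} - \bar w_{ij})^2} with \eqn{r_{ij} = \frac{n}{n-1}
#' \bar w_{ij}}. When all off-diagonal correlations are exactly zero the
#' ratio is 0/0 and full shrinkage (\eqn{\lambda = 1}) is returned.
#'
#' In a two-table analysis one joint intensity is estimated from the
#' column-concatenated `[X | Y]` matrix and reused for the X-block, Y-block
#' and cross-block, so that all blocks of the joint correlation matrix are
#' shrunk coherently.
#'
#' @param data numeric matrix, `n x p`, with `n >= 3` and no constant column.
#' @param min_lambda lower floor applied after clipping; the default `0`
#'   applies no floor. A strictly positive floor guarantees a positive
#'   definite shrunk correlation matrix even for rank-deficient data.
#'
#' @return shrinkage intensity in `[min_lambda, 1]`.
#' @export
shrink_intensity <- function(data, min_lambda = 0) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 3) stop("insufficient samples: need n >= 3 to estimate the intensity")
  sdev <- apply(data, 2, stats::sd)
  bad <- which(sdev == 0 | !is.finite(sdev))
  if (length(bad) > 0) {
    stop("degenerate variable: zero variance in column ",
         paste(bad, collapse = ", "))
  }
  xs <- scale(data)
  w_bar <- crossprod(xs) / n          # mean over samples of w_kij
  w2 <- crossprod(xs^2)               # sum over samples of w_kij^2
  var_r <- n / (n - 1)^3 * (w2 - n * w_bar^2)
  r <- n / (n - 1) * w_bar
  diag(var_r) <- 0
  diag(r) <- 0
  denom <- sum(r^2)
  if (denom == 0) return(1)           # no off-diagonal correlation: 0/0 -> 1
  lam <- sum(var_r) / denom
  max(min_lambda, min(1, max(0, lam)))
}

#' Fit a low-rank shrinkage correlation model
#'
#' Represents the shrunk correlation estimate
#' \eqn{R = \lambda I + (1 - \lambda) R_{emp}} in the factored form
#' \deqn{R = \lambda (I_p + U N U^T),}
#' with \eqn{U} the `p x r` matrix of right singular vectors of the
#' standardized data and \eqn{N = \mathrm{diag}\big(\frac{1-\lambda}{\lambda}
#' \frac{d_k^2}{n-1}\big)} built from the singular values \eqn{d_k}. The
#' rank is at most `min(n - 1, p)`, so for `n << p` the dense `p x p`
#' matrix is never formed. Singular values below `1e-12` times the largest
#' are dropped.
#'
#' @param data numeric matrix, `n x p`.
#' @param lambda_shrink shrinkage intensity in `(0, 1]`, or `"auto"` to
#'   estimate it with [shrink_intensity()] from `data` itself.
#' @param min_lambda forwarded to [shrink_intensity()] when
#'   `lambda_shrink = "auto"`.
#'
#' @return An object of class `"shrinkage_cor"`: a list with
#'   `lambda` (intensity), `U` (`p x r`, orthonormal columns), `N`
#'   (length-`r` nonnegative vector, the diagonal of \eqn{N}), `sdev`,
#'   `center`, `n`, `p`, `r`.
#'
#' @seealso [inv_sqrt_mult()], [shrinkage_cor_dense()]
#' @export
fit_shrinkage_model <- function(data, lambda_shrink = "auto", min_lambda = 0) {
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (identical(lambda_shrink, "auto")) {
    lambda_shrink <- shrink_intensity(data, min_lambda = min_lambda)
  }
  lambda_shrink <- as.numeric(lambda_shrink)
  if (lambda_shrink < 0 || lambda_shrink > 1) {
    stop("'lambda_shrink' must lie in [0, 1]")
  }
  center <- colMeans(data)
  sdev <- apply(data, 2, stats::sd)
  bad <- which(sdev == 0 | !is.finite(sdev))
  if (length(bad) > 0) {
    stop("degenerate variable: zero variance in column ",
         paste(bad, collapse = ", "))
  }
  xs <- scale(data, center = center, scale = sdev)
  sv <- svd(xs, nu = 0)
  keep <- sv$d >= 1e-12 * sv$d[1]
  d <- sv$d[keep]
  U <- sv$v[, keep, drop = FALSE]
  r <- length(d)
  if (lambda_shrink == 0 && r < p) {
    stop("lambda_shrink = 0 with rank ", r, " < ", p,
         " variables gives a singular estimate; use a positive intensity")
  }
  N <- if (lambda_shrink == 1) {
    rep(0, r)  # reconstruction is exactly the identity
  } else {
    (1 - lambda_shrink) / lambda_shrink * d^2 / (n - 1)
  }
  structure(list(lambda = lambda_shrink, U = U, N = N, sdev = sdev,
                 center = center, n = n, p = p, r = r),
            class = "shrinkage_cor")
}

# R^s M for s in {-1, -1/2, 1/2}: lambda^s (M + U diag((1+N)^s - 1) U^T M).
# Only p x r and r x d intermediates are formed.
shrink_pow_mult <- function(model, M, s) {
  M <- as.matrix(M)
  if (nrow(M) != model$p) {
    stop("M has ", nrow(M), " rows but the model has ", model$p, " variables")
  }
  f <- (1 + model$N)^s - 1
  model$lambda^s * (M + model$U %*% (f * crossprod(model$U, M)))
}

#' Multiply by the inverse square root of a shrunk correlation matrix
#'
#' Computes \eqn{R^{-1/2} M} for a [fit_shrinkage_model()] estimate using the
#' low-rank identity
#' \deqn{R^{-1/2} M = \lambda^{-1/2}\Big(M - U \big(I_r - (I_r + N)^{-1/2}\big)
#'       (U^T M)\Big),}
#' so no `p x p` matrix is ever computed or stored; the peak intermediate
#' sizes are `p x r` and `r x d`. This is the workhorse that makes canonical
#' correlation analysis feasible when variables far outnumber samples.
#'
#' @param model a `"shrinkage_cor"` object.
#' @param M numeric matrix with `p` rows (a vector is treated as one column).
#'
#' @return matrix of the same shape as `M`.
#' @export
inv_sqrt_mult <- function(model, M) {
  stopifnot(inherits(model, "shrinkage_cor"))
  shrink_pow_mult(model, M, -1/2)
}

#' Dense reconstruction of a shrunk correlation matrix
#'
#' Materializes \eqn{R = \lambda (I + U N U^T)} as a dense matrix. Intended
#' for small `p` only (checks against oracles, inspection); the analysis
#' pipeline itself never calls this.
#'
#' @param model a `"shrinkage_cor"` object.
#' @return dense `p x p` correlation matrix.
#' @export
shrinkage_cor_dense <- function(model) {
  stopifnot(inherits(model, "shrinkage_cor"))
  R <- model$lambda * (diag(model$p) +
                         model$U %*% (model$N * t(model$U)))
  (R + t(R)) / 2
}

#' @export
print.shrinkage_cor <- function(x, ...) {
  cat("Shrinkage correlation model\n")
  cat(sprintf("  variables: %d   samples: %d   rank: %d\n", x$p, x$n, x$r))
  cat(sprintf("  shrinkage intensity lambda = %.4f\n", x$lambda))
  invisible(x)
}
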