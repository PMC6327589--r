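#' Joint first and second moments of a paired random vector
#'
#' Container for the population-level inputs of a two-table analysis: means
#' and covariance blocks of the composite vector \eqn{(X^T, Y^T)^T}, i.e.
#' \eqn{\mu_X}, \eqn{\mu_Y}, \eqn{\Sigma_X}, \eqn{\Sigma_Y} and the
#' cross-covariance \eqn{\Sigma_{XY}}. Population mode lets exact moments
#' bypass sampling noise entirely.
#'
#' @param mu_X,mu_Y mean vectors of length `p` and `q`.
#' @param Sigma_X,Sigma_Y within-set covariance matrices (`p x p`, `q x q`);
#'   must be symmetric with strictly positive diagonal.
#' @param Sigma_XY `p x q` cross-covariance matrix.
#' @param check_psd if `TRUE`, additionally verify that the composite
#'   `(p+q) x (p+q)` block matrix is positive semi-definite (smallest
#'   eigenvalue above `-tol`).
#' @param tol symmetry / PSD tolerance.
#'
#' @return An object of class `"joint_moments"`.
#'
#' @examples
#' jm <- joint_moments(c(0, 0), 0, diag(2), matrix(1), matrix(c(0.5, 0), 2, 1))
#' jm$Sigma_XY
#' @export
joint_moments <- function(mu_X, mu_Y, Sigma_X, Sigma_Y, Sigma_XY,
                          check_psd = FALSE, tol = 1e-8) {
  Sigma_X <- as.matrix(Sigma_X)
  Sigma_Y <- as.matrix(Sigma_Y)
  Sigma_XY <- as.matrix(Sigma_XY)
  p <- nrow(Sigma_X)
  q <- nrow(Sigma_Y)
  mu_X <- rep_len(as.numeric(mu_X), p)
  mu_Y <- rep_len(as.numeric(mu_Y), q)
  check_block <- function(S, name) {
    if (nrow(S) != ncol(S)) stop("'", name, "' must be square")
    scale <- max(abs(S), 1)
    if (max(abs(S - t(S))) > tol * scale) {
      stop("'", name, "' is not symmetric within tolerance")
    }
    if (any(diag(S) <= 0)) {
      stop("degenerate variable: non-positive variance in '", name, "'")
    }
  }
  check_block(Sigma_X, "Sigma_X")
  check_block(Sigma_Y, "Sigma_Y")
  if (nrow(Sigma_XY) != p || ncol(Sigma_XY) != q) {
    stop("'Sigma_XY' must be ", p, " x ", q)
  }
  obj <- structure(list(mu_X = mu_X, mu_Y = mu_Y,
                        Sigma_X = Sigma_X, Sigma_Y = Sigma_Y,
                        Sigma_XY = Sigma_XY, p = p, q = q),
                   class = "joint_moments")
  if (check_psd && composite_min_eigenvalue(obj) < -tol) {
    stop("composite covariance matrix is not positive semi-definite")
  }
  obj
}

#' Smallest eigenvalue of the composite covariance matrix
#'
#' On-demand PSD diagnostic for a [joint_moments()] object: assembles the
#' composite block matrix and returns its smallest eigenvalue.
#'
#' @param moments a `"joint_moments"` object.
#' @return smallest eigenvalue (negative values indicate an invalid joint
#'   covariance).
#' @export
composite_min_eigenvalue <- function(moments) {
  stopifnot(inherits(moments, "joint_moments"))
  S <- rbind(cbind(moments$Sigma_X, moments$Sigma_XY),
             cbind(t(moments$Sigma_XY), moments$Sigma_Y))
  min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Empirical joint moments of two matched data matrices
#'
#' Convenience estimator: unbiased (n-1 denominator) covariance blocks and
#' sample means of two matrices with matched rows.
#'
#' @param X,Y numeric matrices with equal row counts.
#' @return a `"joint_moments"` object.
#' @export
empirical_moments <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2) stop("at least 2 samples are required")
  joint_moments(colMeans(X), colMeans(Y),
                stats::cov(X), stats::cov(Y), stats::cov(X, Y))
}
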