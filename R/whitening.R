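#' Split a covariance matrix into variances and correlations
#'
#' Decomposes a covariance matrix as \eqn{\Sigma = V^{1/2} P V^{1/2}}, where
#' \eqn{V} is the diagonal matrix of variances and \eqn{P} the correlation
#' matrix with exactly unit diagonal. This separation underlies the whole
#' correlation-based whitening family: variances and correlation structure
#' enter the transforms through different factors.
#'
#' @param Sigma symmetric positive semi-definite covariance matrix.
#'
#' @return A list of class `"corvar_decomposition"` with components
#'   \describe{
#'     \item{V}{numeric vector of variances (the diagonal of \eqn{\Sigma}).}
#'     \item{P}{correlation matrix with unit diagonal.}
#'   }
#'
#' @examples
#' d <- decompose_covariance(matrix(c(4, 1.2, 1.2, 1), 2, 2))
#' d$V          # 4 1
#' d$P[1, 2]    # 0.6
#' @export
decompose_covariance <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma)) {
    stop("'Sigma' must be square")
  }
  v <- diag(Sigma)
  bad <- which(v <= 0)
  if (length(bad) > 0) {
    stop("degenerate variable: non-positive variance at index ",
         paste(bad, collapse = ", "))
  }
  s <- sqrt(v)
  P <- Sigma / tcrossprod(s)
  # force exact unit diagonal and symmetry (guards tiny rounding)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  structure(list(V = v, P = P), class = "corvar_decomposition")
}

#' Symmetric matrix power of a positive semi-definite matrix
#'
#' Computes \eqn{M^{e}} for \eqn{e \in \{-1/2, 1/2\}} (and other real
#' exponents) through the symmetric eigendecomposition, so that the result is
#' itself symmetric. Cholesky-based roots are deliberately not used: the
#' whitening and loading formulas require the unique symmetric square root of
#' a correlation matrix.
#'
#' @param M symmetric positive semi-definite matrix.
#' @param exponent real exponent, typically `-1/2` or `1/2`.
#' @param strict logical; if `TRUE` and `exponent < 0`, eigenvalues below
#'   `floor_frac` times the largest eigenvalue raise an error (advising
#'   shrinkage estimation). If `FALSE` such eigenvalues are clamped to the
#'   floor before inversion.
#' @param floor_frac relative eigenvalue floor, default `1e-10`.
#'
#' @return symmetric matrix \eqn{M^{e}}.
#' @export
matrix_power_psd <- function(M, exponent, strict = FALSE, floor_frac = 1e-10) {
  M <- as.matrix(M)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- max(abs(vals)) * .Machine$double.eps * nrow(M) * 10
  if (min(vals) < -max(tol, 1e-8 * max(abs(vals)))) {
    stop("matrix is not positive semi-definite (eigenvalue ",
         format(min(vals)), ")")
  }
  vals[vals < 0] <- 0
  if (exponent < 0) {
    flr <- floor_frac * max(vals)
    if (any(vals < flr)) {
      if (strict) {
        stop("matrix is rank deficient (eigenvalue below ",
             format(flr), "); consider shrinkage estimation")
      }
      vals[vals < flr] <- flr
    }
  }
  out <- e$vectors %*% (vals^exponent * t(e$vectors))
  (out + t(out)) / 2
}

#' Construct a whitening transform from a covariance matrix
#'
#' Builds a member of the correlation-based whitening family
#' \deqn{W = Q P^{-1/2} V^{-1/2},}
#' where the orthogonal rotation \eqn{Q} selects the particular sphering
#' method. `rotation = "zca_cor"` takes \eqn{Q = I} (correlation Mahalanobis
#' whitening); `rotation = "pca_cor"` takes \eqn{Q = G^T} from the spectral
#' decomposition \eqn{P = G \Theta G^T}, with eigenvalues sorted in
#' decreasing order and the sign of each row of \eqn{Q} flipped so that the
#' diagonal of \eqn{Q} is nonnegative (the minimal-rotation convention that
#' removes the eigenvector sign ambiguity). An explicit rotation matrix with
#' orthonormal rows may also be supplied, which is how the canonical
#' correlation rotations enter.
#'
#' Alongside \eqn{W} the mixing (coloring) matrix \eqn{\Phi = Q P^{1/2}
#' V^{1/2}} and the correlation-loadings \eqn{\Psi = Q P^{1/2}} are returned;
#' \eqn{\Phi^T} inverts a square \eqn{W}, and the squared entries of each
#' column of \eqn{\Psi} sum to one for square transforms.
#'
#' @param Sigma covariance matrix of the variables to be whitened.
#' @param rotation `"zca_cor"`, `"pca_cor"`, or an explicit `k x p` matrix
#'   with orthonormal rows.
#' @param center optional mean vector stored with the transform and used by
#'   [apply_transform()]; defaults to the zero vector.
#' @param strict passed to [matrix_power_psd()] for the inverse square root.
#'
#' @return An object of class `"whitening_transform"`: a list with `Q`, `W`,
#'   `Phi`, `Psi`, `center`, and the `V`, `P` factors of `Sigma`.
#'
#' @examples
#' Sigma <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
#' wt <- make_whitening(Sigma, "zca_cor")
#' wt$W %*% Sigma %*% t(wt$W)   # identity
#' @export
make_whitening <- function(Sigma, rotation = c("zca_cor", "pca_cor"),
                           center = NULL, strict = FALSE) {
  dec <- decompose_covariance(Sigma)
  p <- length(dec$V)
  if (is.character(rotation)) {
    rotation <- match.arg(rotation)
    if (rotation == "zca_cor") {
      Q <- diag(p)
    } else {
      es <- eigen(dec$P, symmetric = TRUE)   # eigenvalues descending
      Q <- t(es$vectors)
      flips <- sign(diag(Q))
      flips[flips == 0] <- 1
      Q <- Q * flips
    }
  } else {
    Q <- as.matrix(rotation)
    if (ncol(Q) != p) {
      stop("explicit rotation must have ", p, " columns")
    }
    gram <- tcrossprod(Q)
    if (max(abs(gram - diag(nrow(Q)))) > 1e-8) {
      stop("explicit rotation must have orthonormal rows (Q Q^T = I)")
    }
  }
  if (is.null(center)) center <- numeric(p)
  Pn <- matrix_power_psd(dec$P, -1/2, strict = strict)
  Pp <- matrix_power_psd(dec$P, 1/2)
  sv <- sqrt(dec$V)
  W <- (Q %*% Pn) %*% diag(1 / sv, p)
  Phi <- (Q %*% Pp) %*% diag(sv, p)
  Psi <- Q %*% Pp
  structure(list(Q = Q, W = W, Phi = Phi, Psi = Psi,
                 center = center, V = dec$V, P = dec$P),
            class = "whitening_transform")
}

#' Apply a whitening transform to data
#'
#' Maps each row \eqn{x_i} of a data matrix to \eqn{W (x_i - \mu)}. Because
#' the transform acts on centered data, the result is invariant under
#' location translation of the input (when the center is refitted
#' accordingly), mirroring the translation invariance of correlation-based
#' methods.
#'
#' @param transform a `"whitening_transform"` object.
#' @param data numeric matrix, `n x p`.
#' @param center optional override of the stored center vector.
#'
#' @return `n x k` matrix of whitened rows.
#' @export
apply_transform <- function(transform, data, center = NULL) {
  stopifnot(inherits(transform, "whitening_transform"))
  data <- as.matrix(data)
  p <- ncol(transform$W)
  if (ncol(data) != p) {
    stop("data has ", ncol(data), " columns but the transform expects ", p)
  }
  if (is.null(center)) center <- transform$center
  tcrossprod(sweep(data, 2, center, "-"), transform$W)
}
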