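#' Correlation-adjusted cross-correlation matrix K
#'
#' Computes \eqn{K = P_X^{-1/2}\, P_{XY}\, P_Y^{-1/2}}, the cross-correlation
#' matrix between the two individually whitened vectors before any rotation
#' is applied. The singular values of \eqn{K} are the magnitudes of the
#' canonical correlations.
#'
#' @param P_X,P_Y within-set correlation matrices (`p x p`, `q x q`).
#' @param P_XY `p x q` cross-correlation matrix.
#' @param strict passed to [matrix_power_psd()]; in strict mode a
#'   rank-deficient `P_X` or `P_Y` raises an error advising shrinkage.
#'
#' @return `p x q` matrix `K`.
#' @export
compute_K <- function(P_X, P_XY, P_Y, strict = FALSE) {
  P_XY <- as.matrix(P_XY)
  if (nrow(P_XY) != nrow(as.matrix(P_X)) ||
      ncol(P_XY) != nrow(as.matrix(P_Y))) {
    stop("'P_XY' dimensions do not match 'P_X' and 'P_Y'")
  }
  matrix_power_psd(P_X, -1/2, strict = strict) %*% P_XY %*%
    matrix_power_psd(P_Y, -1/2, strict = strict)
}

#' Low-rank computation of the K matrix under joint shrinkage
#'
#' Equivalent to [compute_K()] on the dense shrunk correlation blocks, but
#' implemented entirely through the low-rank representation so that no
#' `p x p` or `q x q` matrix is materialized. The shrunk cross block is
#' \eqn{(1-\lambda)\widehat{R}_{XY} = \frac{1-\lambda}{n-1}\, X_s^T Y_s}
#' (with `X_s`, `Y_s` the standardized data), and the two inverse square
#' roots are applied with [inv_sqrt_mult()] on the left and, via
#' transposition, on the right.
#'
#' @param model_X,model_Y `"shrinkage_cor"` models for the two blocks; they
#'   must share the same (joint) shrinkage intensity.
#' @param crossprod_xy `p x q` matrix of raw cross-products of the
#'   standardized data, \eqn{X_s^T Y_s}.
#'
#' @return `p x q` matrix `K`.
#' @export
compute_K_lowrank <- function(model_X, model_Y, crossprod_xy) {
  stopifnot(inherits(model_X, "shrinkage_cor"),
            inherits(model_Y, "shrinkage_cor"))
  if (abs(model_X$lambda - model_Y$lambda) > 1e-12) {
    stop("the two blocks must share one joint shrinkage intensity (got ",
         format(model_X$lambda), " and ", format(model_Y$lambda), ")")
  }
  if (model_X$n != model_Y$n) {
    stop("the two blocks were fitted on different sample counts")
  }
  crossprod_xy <- as.matrix(crossprod_xy)
  if (nrow(crossprod_xy) != model_X$p || ncol(crossprod_xy) != model_Y$p) {
    stop("'crossprod_xy' must be ", model_X$p, " x ", model_Y$p)
  }
  n <- model_X$n
  R_xy <- (1 - model_X$lambda) / (n - 1) * crossprod_xy
  t(inv_sqrt_mult(model_Y, t(inv_sqrt_mult(model_X, R_xy))))
}

#' Sign-resolved singular value decomposition
#'
#' Decomposes \eqn{K = Q_X^T \Lambda\, Q_Y} with semi-orthogonal rotations
#' (`m x p` and `m x q`, `m = min(p, q)`) and signed values
#' \eqn{\lambda_i \in [-1, 1]}. The sign ambiguity of the SVD is resolved by
#' simultaneously flipping row signs of both rotations and the sign of
#' \eqn{\lambda_i} so that both rotation matrices have a nonnegative
#' diagonal — the rotations closest to the identity. Concretely, with
#' singular vectors \eqn{u_i, v_i}: \eqn{s_i = \mathrm{sign}(u_{ii})},
#' \eqn{t_i = \mathrm{sign}(v_{ii})} (zero counts as +1), row `i` of `Q_X`
#' is \eqn{s_i u_i^T}, row `i` of `Q_Y` is \eqn{t_i v_i^T}, and
#' \eqn{\lambda_i = s_i t_i d_i}. The magnitudes \eqn{|\lambda_i|} are
#' exactly the singular values, ordered decreasingly (ties keep the
#' underlying SVD order).
#'
#' For `K = 0` (or exactly tied singular values) the decomposition is not
#' unique; the deterministic output of the underlying LAPACK SVD plus the
#' sign rule is returned.
#'
#' @param K numeric `p x q` matrix with finite entries.
#'
#' @return list with `Q_X` (`m x p`), `Q_Y` (`m x q`), `lambda` (length `m`).
#' @export
svd_signed <- function(K) {
  K <- as.matrix(K)
  if (any(!is.finite(K))) stop("'K' must have finite entries")
  m <- min(dim(K))
  sv <- svd(K, nu = m, nv = m)
  u <- sv$u
  v <- sv$v
  s <- sign(u[cbind(seq_len(m), seq_len(m))])
  t_ <- sign(v[cbind(seq_len(m), seq_len(m))])
  s[s == 0] <- 1
  t_[t_ == 0] <- 1
  list(Q_X = t(u) * s,
       Q_Y = t(v) * t_,
       lambda = s * t_ * sv$d[seq_len(m)])
}

#' Canonical correlation analysis as a whitening transformation
#'
#' Fits CCA by simultaneous whitening of both tables: estimate the joint
#' second moments, form the correlation-adjusted cross-correlation matrix
#' \eqn{K = P_X^{-1/2} P_{XY} P_Y^{-1/2}}, take its sign-resolved SVD
#' \eqn{K = Q_X^T \Lambda Q_Y} ([svd_signed()]), and assemble the canonical
#' whitening matrices \eqn{W_X = Q_X P_X^{-1/2} V_X^{-1/2}} (rows are the
#' canonical directions \eqn{\alpha_i}), the loadings
#' \eqn{\Phi = Q P^{1/2} V^{1/2}} and correlation-loadings
#' \eqn{\Psi = Q P^{1/2}}. The canonical correlations \eqn{\lambda_i} are
#' signed: they are the regression coefficients linking the paired
#' CCA-whitened components, so a negative association is reported as a
#' negative \eqn{\lambda_i} rather than hidden in a direction flip.
#'
#' Estimators:
#' \describe{
#'   \item{`"empirical"`}{unbiased sample moments; requires
#'     `n > max(p, q)`, otherwise an error advises shrinkage.}
#'   \item{`"shrinkage"`}{one joint shrinkage intensity is estimated from
#'     the column-concatenated `[X | Y]` matrix ([shrink_intensity()]) and
#'     applied to all three correlation blocks. When `n <= max(p, q)` (or
#'     `use_lowrank = TRUE`) every product involving \eqn{R^{\pm 1/2}} is
#'     carried out through the low-rank representation, so the memory and
#'     time cost is governed by `n`, not by `p` or `q`.}
#'   \item{`"auto"`}{empirical when `n > max(p, q)`, shrinkage otherwise.}
#' }
#'
#' Variances are never shrunk: shrinkage acts on the correlation matrix
#' only, and the empirical standard deviations (n-1 denominator) enter
#' through \eqn{V^{\pm 1/2}}.
#'
#' @param X,Y numeric matrices with matched rows (`n x p`, `n x q`).
#' @param estimator `"auto"`, `"empirical"`, or `"shrinkage"`.
#' @param lambda_shrink shrinkage intensity override in `(0, 1]`, or
#'   `"auto"` (default) to estimate it from the data.
#' @param standardize if `TRUE`, columns are z-scored before fitting (the
#'   canonical correlations are unaffected; directions are then expressed on
#'   the standardized scale).
#' @param use_lowrank force (`TRUE`) or forbid (`FALSE`) the low-rank
#'   algebra; `NULL` (default) selects it automatically when
#'   `n <= max(p, q)`.
#'
#' @return An object of class `"cca"`; see [cca_from_moments()] for the
#'   fields.
#'
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200, 5)
#' Y <- X[, 1:3] + matrix(rnorm(200 * 3), 200, 3)
#' fit <- cca_fit(X, Y)
#' fit$lambda
#' @export
cca_fit <- function(X, Y, estimator = c("auto", "empirical", "shrinkage"),
                    lambda_shrink = "auto", standardize = FALSE,
                    use_lowrank = NULL) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3) stop("insufficient samples: need n >= 3")
  p <- ncol(X); q <- ncol(Y)
  if (estimator == "auto") {
    estimator <- if (n > max(p, q)) "empirical" else "shrinkage"
  }
  center_X <- colMeans(X); center_Y <- colMeans(Y)
  scale_X <- rep(1, p); scale_Y <- rep(1, q)
  if (standardize) {
    scale_X <- apply(X, 2, stats::sd)
    scale_Y <- apply(Y, 2, stats::sd)
    if (any(scale_X == 0) || any(scale_Y == 0)) {
      stop("degenerate variable: zero variance column cannot be standardized")
    }
    X <- scale(X, center = center_X, scale = scale_X)
    Y <- scale(Y, center = center_Y, scale = scale_Y)
  }

  if (estimator == "empirical") {
    if (n <= max(p, q)) {
      stop("empirical estimation needs n > max(p, q) (n = ", n,
           ", p = ", p, ", q = ", q, "); use estimator = \"shrinkage\"")
    }
    fit <- cca_from_moments(empirical_moments(X, Y))
    meta <- list(estimator = "empirical", lambda_shrink = NA_real_,
                 n = n, lowrank = FALSE)
  } else {
    if (identical(lambda_shrink, "auto")) {
      lambda_shrink <- shrink_intensity(cbind(X, Y))
    }
    lowrank <- if (is.null(use_lowrank)) n <= max(p, q) else isTRUE(use_lowrank)
    fit <- if (lowrank) {
      cca_shrinkage_lowrank(X, Y, lambda_shrink)
    } else {
      cca_shrinkage_dense(X, Y, lambda_shrink)
    }
    meta <- list(estimator = "shrinkage", lambda_shrink = lambda_shrink,
                 n = n, lowrank = lowrank)
  }
  if (standardize) {
    # report centers/scales of the original data so scores() can reproduce
    # the internal standardization
    fit$mu_X <- center_X
    fit$mu_Y <- center_Y
  }
  fit$scale_X <- scale_X
  fit$scale_Y <- scale_Y
  fit$meta <- utils::modifyList(fit$meta, meta)
  fit$meta$standardize <- standardize
  fit
}

#' Canonical correlation analysis from exact joint moments
#'
#' Population-mode fit: given exact means and covariance blocks, compute the
#' signed canonical correlations and all derived matrices without sampling.
#'
#' @param moments a [joint_moments()] object.
#' @param strict passed to [matrix_power_psd()].
#'
#' @return An object of class `"cca"` with fields
#'   \describe{
#'     \item{m}{number of canonical components, `min(p, q)`.}
#'     \item{lambda}{signed canonical correlations, `|lambda|` decreasing.}
#'     \item{Q_X, Q_Y}{`m x p` / `m x q` semi-orthogonal rotations with
#'       nonnegative diagonals.}
#'     \item{W_X, W_Y}{canonical whitening matrices; row `i` holds the
#'       canonical direction \eqn{\alpha_i} / \eqn{\beta_i}.}
#'     \item{Phi_X, Phi_Y}{loadings (covariances between canonical and
#'       original variables).}
#'     \item{Psi_X, Psi_Y}{correlation-loadings.}
#'     \item{mu_X, mu_Y}{fitted centers.}
#'     \item{meta}{estimator description.}
#'   }
#' @export
cca_from_moments <- function(moments, strict = FALSE) {
  stopifnot(inherits(moments, "joint_moments"))
  dx <- decompose_covariance(moments$Sigma_X)
  dy <- decompose_covariance(moments$Sigma_Y)
  P_XY <- moments$Sigma_XY / tcrossprod(sqrt(dx$V), sqrt(dy$V))
  K <- compute_K(dx$P, P_XY, dy$P, strict = strict)
  assemble_cca_dense(svd_signed(K), dx, dy,
                     moments$mu_X, moments$mu_Y,
                     meta = list(estimator = "population",
                                 lambda_shrink = NA_real_))
}

# dense assembly of W/Phi/Psi from a signed SVD and the two V/P splits
assemble_cca_dense <- function(ss, dx, dy, mu_X, mu_Y, meta) {
  p <- length(dx$V); q <- length(dy$V)
  Pxn <- matrix_power_psd(dx$P, -1/2); Pxp <- matrix_power_psd(dx$P, 1/2)
  Pyn <- matrix_power_psd(dy$P, -1/2); Pyp <- matrix_power_psd(dy$P, 1/2)
  sx <- sqrt(dx$V); sy <- sqrt(dy$V)
  QxPn <- ss$Q_X %*% Pxn; QxPp <- ss$Q_X %*% Pxp
  QyPn <- ss$Q_Y %*% Pyn; QyPp <- ss$Q_Y %*% Pyp
  structure(list(
    m = length(ss$lambda), lambda = ss$lambda,
    Q_X = ss$Q_X, Q_Y = ss$Q_Y,
    W_X = sweep(QxPn, 2, sx, "/"), W_Y = sweep(QyPn, 2, sy, "/"),
    Phi_X = sweep(QxPp, 2, sx, "*"), Phi_Y = sweep(QyPp, 2, sy, "*"),
    Psi_X = QxPp, Psi_Y = QyPp,
    mu_X = mu_X, mu_Y = mu_Y,
    scale_X = rep(1, p), scale_Y = rep(1, q),
    meta = meta), class = "cca")
}

# dense shrinkage path: small enough dimensions to materialize the blocks
cca_shrinkage_dense <- function(X, Y, lambda_shrink) {
  p <- ncol(X); q <- ncol(Y)
  shrink <- function(R) {
    lambda_shrink * diag(nrow(R)) + (1 - lambda_shrink) * R
  }
  dx <- list(V = apply(X, 2, stats::var), P = shrink(stats::cor(X)))
  dy <- list(V = apply(Y, 2, stats::var), P = shrink(stats::cor(Y)))
  P_XY <- (1 - lambda_shrink) * stats::cor(X, Y)
  K <- compute_K(dx$P, P_XY, dy$P)
  assemble_cca_dense(svd_signed(K), dx, dy, colMeans(X), colMeans(Y),
                     meta = list(estimator = "shrinkage",
                                 lambda_shrink = lambda_shrink))
}

# low-rank shrinkage path: never materializes p x p or q x q matrices
cca_shrinkage_lowrank <- function(X, Y, lambda_shrink) {
  mx <- fit_shrinkage_model(X, lambda_shrink)
  my <- fit_shrinkage_model(Y, lambda_shrink)
  Xs <- scale(X, center = mx$center, scale = mx$sdev)
  Ys <- scale(Y, center = my$center, scale = my$sdev)
  K <- compute_K_lowrank(mx, my, crossprod(Xs, Ys))
  ss <- svd_signed(K)
  # W = Q R^{-1/2} V^{-1/2}, Phi = Q R^{1/2} V^{1/2}, Psi = Q R^{1/2},
  # with R^{+-1/2} applied through the factored representation
  QxPn <- t(shrink_pow_mult(mx, t(ss$Q_X), -1/2))
  QxPp <- t(shrink_pow_mult(mx, t(ss$Q_X), 1/2))
  QyPn <- t(shrink_pow_mult(my, t(ss$Q_Y), -1/2))
  QyPp <- t(shrink_pow_mult(my, t(ss$Q_Y), 1/2))
  structure(list(
    m = length(ss$lambda), lambda = ss$lambda,
    Q_X = ss$Q_X, Q_Y = ss$Q_Y,
    W_X = sweep(QxPn, 2, mx$sdev, "/"), W_Y = sweep(QyPn, 2, my$sdev, "/"),
    Phi_X = sweep(QxPp, 2, mx$sdev, "*"), Phi_Y = sweep(QyPp, 2, my$sdev, "*"),
    Psi_X = QxPp, Psi_Y = QyPp,
    mu_X = mx$center, mu_Y = my$center,
    scale_X = rep(1, ncol(X)), scale_Y = rep(1, ncol(Y)),
    meta = list(estimator = "shrinkage", lambda_shrink = lambda_shrink)),
    class = "cca")
}

#' Canonical scores
#'
#' Projects data onto the canonical directions: row `i` of the score matrix
#' is \eqn{W (x_i - \mu)} (after the model's standardization, if any). Under
#' a full-rank empirical fit the in-sample correlation of paired score
#' columns equals \eqn{\lambda_i} and distinct pairs are uncorrelated.
#'
#' @param model a `"cca"` object.
#' @param X,Y data matrices with the fitted numbers of columns.
#'
#' @return list with `X` and `Y`, each `n x m`.
#' @export
cca_scores <- function(model, X, Y) {
  stopifnot(inherits(model, "cca"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(model$W_X) || ncol(Y) != ncol(model$W_Y)) {
    stop("data dimensions do not match the fitted model")
  }
  Xc <- sweep(sweep(X, 2, model$mu_X, "-"), 2, model$scale_X, "/")
  Yc <- sweep(sweep(Y, 2, model$mu_Y, "-"), 2, model$scale_Y, "/")
  list(X = tcrossprod(Xc, model$W_X), Y = tcrossprod(Yc, model$W_Y))
}

#' Predictive MSE reduction of the canonical regression
#'
#' For CCA-whitened variables the decrease in predictive mean squared error
#' from using one table to predict the other is
#' \eqn{\Delta = \sum_i \lambda_i^2 = \mathrm{Tr}(K^T K)}; each
#' \eqn{\lambda_i^2} is the variable importance of canonical component `i`.
#'
#' @param lambdas numeric vector of signed canonical correlations in
#'   `[-1, 1]`, or a `"cca"` object.
#'
#' @return \eqn{\Delta}, with the per-component \eqn{\lambda_i^2} attached
#'   as attribute `"importance"`.
#' @export
delta_mse <- function(lambdas) {
  if (inherits(lambdas, "cca")) lambdas <- lambdas$lambda
  if (any(abs(lambdas) > 1 + 1e-8)) {
    stop("canonical correlations must lie in [-1, 1]")
  }
  structure(sum(lambdas^2), importance = lambdas^2)
}

#' Best linear multivariate predictor
#'
#' The optimal linear predictor of `Y` from `X` under squared error, given
#' joint moments: coefficients \eqn{b = \Sigma_X^{-1} \Sigma_{XY}},
#' intercept \eqn{a = \mu_Y - b^T \mu_X}, and the reduction in predictive
#' MSE relative to the intercept-only model
#' \eqn{\Delta = \mathrm{Tr}(\Sigma_{YX} \Sigma_X^{-1} \Sigma_{XY})}.
#' With whitened inputs `b` equals the cross-correlation matrix, and with
#' CCA-whitened inputs it is `diag(lambda)` — the canonical correlations act
#' as regression coefficients.
#'
#' @param moments a [joint_moments()] object with invertible `Sigma_X`.
#'
#' @return list of class `"regression_summary"`: `a` (intercept), `b`
#'   (`p x q` coefficients), `delta`, `mse_zero` (= Tr(\eqn{\Sigma_Y})),
#'   `mse_all`.
#' @export
optimal_linear_predictor <- function(moments) {
  stopifnot(inherits(moments, "joint_moments"))
  b <- tryCatch(solve(moments$Sigma_X, moments$Sigma_XY),
                error = function(e) stop("'Sigma_X' is singular: ",
                                         conditionMessage(e)))
  a <- moments$mu_Y - drop(crossprod(b, moments$mu_X))
  delta <- sum(moments$Sigma_XY * b)   # Tr(Sigma_YX Sigma_X^{-1} Sigma_XY)
  mse_zero <- sum(diag(moments$Sigma_Y))
  structure(list(a = a, b = b, delta = delta,
                 mse_zero = mse_zero, mse_all = mse_zero - delta),
            class = "regression_summary")
}

#' @export
print.cca <- function(x, ...) {
  cat("Canonical correlation analysis (whitening formulation)\n")
  cat(sprintf("  components: %d   estimator: %s", x$m, x$meta$estimator))
  if (identical(x$meta$estimator, "shrinkage")) {
    cat(sprintf(" (intensity %.4f)", x$meta$lambda_shrink))
  }
  cat("\n  signed canonical correlations:\n")
  print(round(x$lambda, 4))
  invisible(x)
}
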