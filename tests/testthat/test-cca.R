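test_that("K matrix matches its dense oracle and trivial cases", {
  expect_equal(compute_K(diag(2), diag(c(0.5, -0.3)), diag(2)),
               diag(c(0.5, -0.3)))
  expect_equal(drop(compute_K(matrix(1), matrix(0.42), matrix(1))), 0.42)

  # random 4+3 joint correlation: K from eigen-based inverse roots
  S <- cov2cor(rand_psd(7, seed = 13))
  P_X <- S[1:4, 1:4]; P_Y <- S[5:7, 5:7]; P_XY <- S[1:4, 5:7]
  K <- compute_K(P_X, P_XY, P_Y)
  expect_lt(max(abs(K - oracle_K(P_X, P_XY, P_Y))), 1e-10)
  expect_lte(max(svd(K)$d), 1 + 1e-10)

  sing <- tcrossprod(matrix(rnorm(8), 4, 2))
  sing <- sing / sqrt(tcrossprod(diag(sing)))
  expect_error(compute_K(sing, P_XY, P_Y, strict = TRUE), "shrinkage")
})

test_that("low-rank K equals the dense shrunk-block computation", {
  set.seed(17)
  X <- matrix(rnorm(12 * 30), 12, 30)
  Y <- matrix(rnorm(12 * 8), 12, 8)
  lam <- shrink_intensity(cbind(X, Y))
  mx <- fit_shrinkage_model(X, lam)
  my <- fit_shrinkage_model(Y, lam)
  Xs <- scale(X); Ys <- scale(Y)
  K_lr <- compute_K_lowrank(mx, my, crossprod(Xs, Ys))
  K_dense <- oracle_K(oracle_shrink_cor(X, lam),
                      (1 - lam) * cor(X, Y),
                      oracle_shrink_cor(Y, lam))
  expect_lt(max(abs(K_lr - K_dense)) / max(abs(K_dense)), 1e-8)

  # full shrinkage kills the cross block entirely
  K1 <- compute_K_lowrank(fit_shrinkage_model(X, 1),
                          fit_shrinkage_model(Y, 1), crossprod(Xs, Ys))
  expect_equal(K1, matrix(0, 30, 8))

  # mutually orthogonal centered tables give K = 0
  Po <- unclass(poly(1:12, 9))
  Xo <- Po[, 1:5]; Yo <- Po[, 6:9]
  lamo <- 0.5
  K0 <- compute_K_lowrank(fit_shrinkage_model(Xo, lamo),
                          fit_shrinkage_model(Yo, lamo),
                          crossprod(scale(Xo), scale(Yo)))
  expect_lt(max(abs(K0)), 1e-10)

  expect_error(compute_K_lowrank(fit_shrinkage_model(X, 0.2),
                                 fit_shrinkage_model(Y, 0.7),
                                 crossprod(Xs, Ys)), "joint")
})

test_that("signed SVD resolves the sign ambiguity deterministically", {
  # already in signed diagonal form: nothing to do
  ss <- svd_signed(diag(c(0.5, -0.3)))
  expect_equal(ss$Q_X, diag(2))
  expect_equal(ss$Q_Y, diag(2))
  expect_equal(ss$lambda, c(0.5, -0.3))

  # zero matrix: all lambdas zero, rotations valid with nonnegative diagonal
  ss0 <- svd_signed(matrix(0, 3, 2))
  expect_equal(ss0$lambda, c(0, 0))
  expect_true(all(diag(ss0$Q_X) >= 0) && all(diag(ss0$Q_Y) >= 0))
  expect_lt(max(abs(tcrossprod(ss0$Q_Y) - diag(2))), 1e-12)

  set.seed(23)
  K <- matrix(runif(20, -1, 1), 5, 4)
  ss2 <- svd_signed(K)
  recon <- t(ss2$Q_X) %*% diag(ss2$lambda) %*% ss2$Q_Y
  expect_lt(max(abs(recon - K)), 1e-10)
  # flipping a row of Q_X together with the sign of lambda_i is a no-op
  Qx <- ss2$Q_X; lam <- ss2$lambda
  Qx[2, ] <- -Qx[2, ]; lam[2] <- -lam[2]
  expect_lt(max(abs(t(Qx) %*% diag(lam) %*% ss2$Q_Y - K)), 1e-10)

  expect_error(svd_signed(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("empirical fit reproduces the classical generalized-eigenproblem CCA", {
  set.seed(29)
  X <- matrix(rnorm(200 * 5), 200, 5)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  Y[, 1] <- Y[, 1] + X[, 1]
  Y[, 2] <- Y[, 2] - 0.5 * X[, 2]
  fit <- cca_fit(X, Y, estimator = "empirical")
  expect_equal(abs(fit$lambda), oracle_classical_cca(X, Y), tolerance = 1e-10)

  # model invariants under the fitted (empirical) moments
  expect_lt(max(abs(fit$W_X %*% cov(X) %*% t(fit$W_X) - diag(4))), 1e-10)
  expect_lt(max(abs(fit$W_Y %*% cov(Y) %*% t(fit$W_Y) - diag(4))), 1e-10)
  expect_lt(max(abs(fit$W_X %*% cov(X, Y) %*% t(fit$W_Y) -
                      diag(fit$lambda))), 1e-10)
  expect_lt(max(abs(tcrossprod(fit$Q_X) - diag(4))), 1e-10)
  expect_true(all(diag(fit$Q_X) >= 0) && all(diag(fit$Q_Y) >= 0))
  expect_true(all(diff(abs(fit$lambda)) <= 1e-12))

  # identical refit is byte-identical: no rotational ambiguity remains
  fit2 <- cca_fit(X, Y, estimator = "empirical")
  expect_identical(fit2$lambda, fit$lambda)
  expect_identical(fit2$W_X, fit$W_X)

  # self-correlation: every canonical correlation is 1
  fs <- cca_fit(X, X, estimator = "empirical")
  expect_equal(fs$lambda, rep(1, 5), tolerance = 1e-8)

  expect_error(cca_fit(X[1:4, ], Y[1:4, ], estimator = "empirical"),
               "shrinkage")
})

test_that("population mode recovers alternating signed correlations exactly", {
  p <- 60; q <- 10
  truth <- rep_len(c(1, -1), q) * 0.9
  jm <- joint_moments(rep(0, p), rep(0, q), diag(p), diag(q),
                      rbind(diag(truth), matrix(0, p - q, q)))
  fit <- cca_from_moments(jm)
  expect_equal(fit$m, 10L)
  expect_equal(fit$lambda, truth, tolerance = 1e-12)
})

test_that("canonical correlations are scale-invariant, directions equivariant", {
  set.seed(37)
  X <- matrix(rnorm(150 * 4), 150, 4)
  Y <- matrix(rnorm(150 * 3), 150, 3) + 0.5 * X[, 1:3]
  fit <- cca_fit(X, Y, estimator = "empirical")
  sc <- c(2, 0.1, 5, 1)
  fit_s <- cca_fit(sweep(X, 2, sc, "*"), Y, estimator = "empirical")
  expect_equal(fit_s$lambda, fit$lambda, tolerance = 1e-10)
  expect_equal(fit_s$W_X, sweep(fit$W_X, 2, sc, "/"), tolerance = 1e-10)

  # squared correlation-loadings per column are bounded by one
  expect_true(all(diag(crossprod(fit$Psi_X)) <= 1 + 1e-10))
  # and equal one on the side where m equals the dimension
  expect_equal(diag(crossprod(fit$Psi_Y)), rep(1, 3), tolerance = 1e-10)

  # standardize flag changes directions but not correlations
  fit_std <- cca_fit(X, Y, estimator = "empirical", standardize = TRUE)
  expect_equal(fit_std$lambda, fit$lambda, tolerance = 1e-10)
})

test_that("scores carry the canonical correlations and ignore translations", {
  set.seed(53)
  X <- matrix(rnorm(300 * 4), 300, 4)
  Y <- matrix(rnorm(300 * 3), 300, 3)
  Y[, 3] <- Y[, 3] + 0.7 * X[, 4]
  fit <- cca_fit(X, Y, estimator = "empirical")
  sc <- cca_scores(fit, X, Y)
  cc <- cor(sc$X, sc$Y)
  expect_equal(diag(cc), fit$lambda, tolerance = 1e-8)
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-8)
  expect_lt(max(abs(cor(sc$X) - diag(3))), 1e-8)

  # translation of the inputs with a refitted center leaves scores unchanged
  Xs <- sweep(X, 2, c(5, -3, 2, 100), "+")
  fit_t <- cca_fit(Xs, Y, estimator = "empirical")
  sc_t <- cca_scores(fit_t, Xs, Y)
  expect_equal(sc_t$X, sc$X, tolerance = 1e-8)

  # scores under standardization reproduce the same correlations
  fit_std <- cca_fit(X, Y, estimator = "empirical", standardize = TRUE)
  sc_std <- cca_scores(fit_std, X, Y)
  expect_equal(diag(cor(sc_std$X, sc_std$Y)), fit_std$lambda,
               tolerance = 1e-8)

  expect_error(cca_scores(fit, X[, 1:2], Y), "dimensions")
})

test_that("predictive MSE reduction follows the Frobenius identity", {
  expect_equal(as.numeric(delta_mse(c(0.6, -0.8))), 1.0)
  expect_equal(as.numeric(delta_mse(numeric(3))), 0)
  expect_equal(attr(delta_mse(c(0.6, -0.8)), "importance"), c(0.36, 0.64))

  set.seed(59)
  K <- matrix(runif(12, -0.5, 0.5), 4, 3) / 2
  lam <- svd_signed(K)$lambda
  expect_equal(as.numeric(delta_mse(lam)), sum(K^2), tolerance = 1e-10)
  expect_error(delta_mse(c(0.5, 1.7)), "\\[-1, 1\\]")
})

test_that("optimal linear predictor minimizes MSE and links to CCA", {
  S <- rand_psd(5, seed = 61)
  jm <- joint_moments(c(1, 2, 3), c(-1, 0), S[1:3, 1:3], S[4:5, 4:5],
                      S[1:3, 4:5])
  reg <- optimal_linear_predictor(jm)
  expect_equal(reg$b, solve(jm$Sigma_X) %*% jm$Sigma_XY, tolerance = 1e-12)
  expect_gte(reg$delta, 0)
  expect_equal(reg$delta, reg$mse_zero - reg$mse_all)

  # numeric optimality: the analytic optimum beats random perturbations
  mse_of <- function(a, b) {
    mudiff <- jm$mu_Y - (a + drop(crossprod(b, jm$mu_X)))
    sum(mudiff^2) + sum(diag(jm$Sigma_Y)) +
      sum(diag(crossprod(b, jm$Sigma_X %*% b))) -
      2 * sum(diag(crossprod(b, jm$Sigma_XY)))
  }
  set.seed(63)
  best <- mse_of(reg$a, reg$b)
  for (i in 1:100) {
    expect_lte(best, mse_of(reg$a + rnorm(2, sd = 0.3),
                            reg$b + matrix(rnorm(6, sd = 0.3), 3, 2)))
  }

  # no predictors: intercept-only model
  jm0 <- joint_moments(c(0, 0), c(1, 1), diag(2), diag(2), matrix(0, 2, 2))
  reg0 <- optimal_linear_predictor(jm0)
  expect_equal(reg0$b, matrix(0, 2, 2))
  expect_equal(reg0$a, c(1, 1))
  expect_equal(reg0$delta, 0)

  # whitened inputs: coefficients equal the cross-correlation matrix
  Pxy <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  regw <- optimal_linear_predictor(
    joint_moments(c(0, 0), c(0, 0), diag(2), diag(2), Pxy))
  expect_equal(regw$b, Pxy)

  # CCA-whitened moments: coefficients are diag(lambda)
  set.seed(67)
  X <- matrix(rnorm(120 * 3), 120, 3)
  Y <- matrix(rnorm(120 * 3), 120, 3) + 0.6 * X
  fit <- cca_fit(X, Y, estimator = "empirical")
  sc <- cca_scores(fit, X, Y)
  regc <- optimal_linear_predictor(empirical_moments(sc$X, sc$Y))
  expect_equal(regc$b, diag(fit$lambda), tolerance = 1e-8)

  expect_error(optimal_linear_predictor(
    joint_moments(c(0, 0), 0, matrix(c(1, 1, 1, 1), 2, 2), matrix(1),
                  matrix(0, 2, 1))), "singular")
})

test_that("loadings agree with simulated covariances between whitened and raw data", {
  set.seed(71)
  Sigma <- rand_psd(3, seed = 71)
  A <- chol(Sigma)
  X <- matrix(rnorm(50000 * 3), 50000, 3) %*% A
  wt <- make_whitening(Sigma, "pca_cor", center = colMeans(X))
  Z <- apply_transform(wt, X)
  # Phi is cov(whitened, original); Monte-Carlo check at large n
  expect_lt(max(abs(cov(Z, X) - wt$Phi)), 0.1)
})
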