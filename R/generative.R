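#' Specification of the two-layer generative CCA model
#'
#' Describes the latent-variable model that generates paired observations
#' with prescribed signed canonical correlations. Level 1 holds independent
#' mean-zero unit-variance latents \eqn{Z^X} (length p), \eqn{Z^Y}
#' (length q) and \eqn{Z^{shared}} (length m = min(p, q)). Level 2 mixes
#' them into the CCA-whitened variables
#' \deqn{\tilde X_i = \sqrt{1-|\lambda_i|}\, Z^X_i +
#'       \sqrt{|\lambda_i|}\, Z^{shared}_i, \qquad
#'       \tilde Y_i = \sqrt{1-|\lambda_i|}\, Z^Y_i +
#'       \sqrt{|\lambda_i|}\, Z^{shared}_i\, \mathrm{sign}(\lambda_i),}
#' (components beyond m are purely non-shared), so that by construction all
#' level-2 components have unit variance and
#' \eqn{\mathrm{cov}(\tilde X_i, \tilde Y_i) = \lambda_i}. Observations are
#' produced by coloring and translation: \eqn{X = \Phi_X^T \tilde X + \mu_X}.
#'
#' The latent distributions are only constrained in their first two moments;
#' `latent_dist = "scaled_t"` draws from a t distribution with `df > 2`
#' degrees of freedom rescaled by \eqn{\sqrt{(df-2)/df}} to unit variance,
#' giving a heavier-tailed variant.
#'
#' @param p,q observed dimensions.
#' @param lambdas signed canonical correlations, length `min(p, q)` (shorter
#'   vectors are padded with zeros), entries in `[-1, 1]`.
#' @param Phi_X,Phi_Y mixing (coloring) matrices, `p x p` / `q x q`;
#'   default identity.
#' @param mu_X,mu_Y location vectors; default zero.
#' @param latent_dist `"gaussian"` or `"scaled_t"`.
#' @param df degrees of freedom for `"scaled_t"`; must exceed 2 for the
#'   variance to exist.
#'
#' @return object of class `"generative_spec"`.
#' @export
generative_spec <- function(p, q, lambdas, Phi_X = NULL, Phi_Y = NULL,
                            mu_X = 0, mu_Y = 0,
                            latent_dist = c("gaussian", "scaled_t"),
                            df = 5) {
  latent_dist <- match.arg(latent_dist)
  m <- min(p, q)
  if (length(lambdas) > m) stop("'lambdas' may have at most min(p, q) entries")
  lambdas <- c(lambdas, rep(0, m - length(lambdas)))
  if (any(abs(lambdas) > 1)) stop("|lambda_i| must not exceed 1")
  if (latent_dist == "scaled_t" && df <= 2) {
    stop("'df' must exceed 2, otherwise the latent variance is infinite")
  }
  if (is.null(Phi_X)) Phi_X <- diag(p)
  if (is.null(Phi_Y)) Phi_Y <- diag(q)
  Phi_X <- as.matrix(Phi_X); Phi_Y <- as.matrix(Phi_Y)
  if (ncol(Phi_X) != p) stop("'Phi_X' must have p columns")
  if (ncol(Phi_Y) != q) stop("'Phi_Y' must have q columns")
  structure(list(p = p, q = q, m = m, lambdas = lambdas,
                 Phi_X = Phi_X, Phi_Y = Phi_Y,
                 mu_X = rep_len(mu_X, p), mu_Y = rep_len(mu_Y, q),
                 latent_dist = latent_dist, df = df),
            class = "generative_spec")
}

# one n x k block of iid mean-0 variance-1 latents
draw_latent_block <- function(n, k, latent_dist, df) {
  z <- switch(latent_dist,
              gaussian = stats::rnorm(n * k),
              scaled_t = stats::rt(n * k, df = df) * sqrt((df - 2) / df))
  matrix(z, n, k)
}

#' Draw the level-1 latent variables
#'
#' Samples `n` independent rows of the three latent blocks \eqn{Z^X},
#' \eqn{Z^Y}, \eqn{Z^{shared}}, each component mean 0 and variance 1 by
#' construction of the chosen distribution.
#'
#' @param spec a [generative_spec()].
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#'
#' @return object of class `"latent_sample"` with matrices `Z_X` (`n x p`),
#'   `Z_Y` (`n x q`), `Z_shared` (`n x m`).
#' @export
sample_latent <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "generative_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  structure(list(Z_X = draw_latent_block(n, spec$p, spec$latent_dist, spec$df),
                 Z_Y = draw_latent_block(n, spec$q, spec$latent_dist, spec$df),
                 Z_shared = draw_latent_block(n, spec$m, spec$latent_dist,
                                              spec$df)),
            class = "latent_sample")
}

#' Mix level-1 latents into the CCA-whitened level-2 variables
#'
#' Adds `Xtilde` and `Ytilde` to a latent sample: component `i` mixes the
#' non-shared and shared latents with weights \eqn{\sqrt{1-|\lambda_i|}} and
#' \eqn{\sqrt{|\lambda_i|}}, the shared part entering `Ytilde` with the sign
#' of \eqn{\lambda_i}. Components beyond `m` (and any with \eqn{\lambda_i=0})
#' are copied from the non-shared latents unchanged.
#'
#' @param latent a `"latent_sample"` with level-1 fields.
#' @param lambdas signed canonical correlations (at most `m` entries).
#'
#' @return the sample with `Xtilde` (`n x p`) and `Ytilde` (`n x q`) added.
#' @export
mix_level2 <- function(latent, lambdas) {
  stopifnot(inherits(latent, "latent_sample"))
  p <- ncol(latent$Z_X); q <- ncol(latent$Z_Y); m <- ncol(latent$Z_shared)
  if (length(lambdas) > m) stop("'lambdas' may have at most m entries")
  lam <- c(lambdas, rep(0, m - length(lambdas)))
  if (any(abs(lam) > 1)) stop("|lambda_i| must not exceed 1")
  wn <- sqrt(1 - abs(lam))    # non-shared weight, components 1..m
  ws <- sqrt(abs(lam))        # shared weight
  Xt <- latent$Z_X
  Yt <- latent$Z_Y
  Xt[, seq_len(m)] <- sweep(latent$Z_X[, seq_len(m), drop = FALSE], 2, wn, "*") +
    sweep(latent$Z_shared, 2, ws, "*")
  Yt[, seq_len(m)] <- sweep(latent$Z_Y[, seq_len(m), drop = FALSE], 2, wn, "*") +
    sweep(latent$Z_shared, 2, ws * sign_or_one(lam), "*")
  latent$Xtilde <- Xt
  latent$Ytilde <- Yt
  latent$lambdas <- lam
  latent
}

sign_or_one <- function(x) {
  s <- sign(x)
  s[s == 0] <- 1
  s
}

#' Color and translate level-2 variables into observations
#'
#' Adds the observed matrices to a latent sample via the coloring transform
#' \eqn{X = \Phi_X^T \tilde X + \mu_X} (applied row-wise), so the population
#' covariance of `X` is \eqn{\Phi_X^T \Phi_X}.
#'
#' @param latent a `"latent_sample"` with level-2 fields (see
#'   [mix_level2()]).
#' @param spec the [generative_spec()] providing `Phi_X`, `Phi_Y`, `mu_X`,
#'   `mu_Y`.
#'
#' @return the sample with `X` (`n x p`) and `Y` (`n x q`) added.
#' @export
color_observe <- function(latent, spec) {
  stopifnot(inherits(latent, "latent_sample"),
            inherits(spec, "generative_spec"))
  if (is.null(latent$Xtilde)) stop("level-2 fields missing; run mix_level2()")
  if (ncol(latent$Xtilde) != nrow(spec$Phi_X)) {
    stop("'Phi_X' does not match the level-2 dimension")
  }
  if (ncol(latent$Ytilde) != nrow(spec$Phi_Y)) {
    stop("'Phi_Y' does not match the level-2 dimension")
  }
  latent$X <- sweep(latent$Xtilde %*% spec$Phi_X, 2, spec$mu_X, "+")
  latent$Y <- sweep(latent$Ytilde %*% spec$Phi_Y, 2, spec$mu_Y, "+")
  latent
}

#' Simulate paired observations from the generative CCA model
#'
#' Runs the full chain [sample_latent()] -> [mix_level2()] ->
#' [color_observe()].
#'
#' @inheritParams sample_latent
#' @return a `"latent_sample"` with all levels populated.
#' @export
simulate_cca_data <- function(spec, n, seed = NULL) {
  color_observe(mix_level2(sample_latent(spec, n, seed = seed),
                           spec$lambdas), spec)
}

#' Simulate the alternating-sign synthetic design
#'
#' Draws matched pairs from a `(p+q)`-variate normal with identity
#' within-set covariances and diagonal cross-covariance whose entries
#' alternate in sign: \eqn{\lambda_1 = \lambda_3 = \cdots = \lambda},
#' \eqn{\lambda_2 = \lambda_4 = \cdots = -\lambda}. Implemented through the
#' generative model with identity coloring, which realizes exactly this
#' block covariance.
#'
#' @param n samples per replicate.
#' @param lam correlation strength, `0 < lam < 1`.
#' @param reps number of independent replicate pairs.
#' @param p,q dimensions (defaults 60 and 10).
#' @param seed optional integer; replicate `r` uses substream seed
#'   `seed + r - 1`.
#'
#' @return list of length `reps`; each element has matrices `X`, `Y` and the
#'   true signed vector is attached as attribute `"lambdas"`.
#' @export
simulate_synthetic_design <- function(n, lam, reps = 1, p = 60, q = 10,
                                      seed = NULL) {
  if (lam <= 0 || lam >= 1) stop("'lam' must lie strictly between 0 and 1")
  m <- min(p, q)
  truth <- rep_len(c(1, -1), m) * lam
  spec <- generative_spec(p, q, truth)
  out <- lapply(seq_len(reps), function(r) {
    s <- if (is.null(seed)) NULL else seed + r - 1
    sim <- simulate_cca_data(spec, n, seed = s)
    list(X = sim$X, Y = sim$Y)
  })
  attr(out, "lambdas") <- truth
  out
}

#' Sign-recovery simulation experiment
#'
#' For each cell of the `(n, lambda)` grid, repeatedly simulates the
#' alternating-sign design ([simulate_synthetic_design()]), fits the
#' shrinkage CCA model, and records the fraction of the `min(p, q)`
#' estimated canonical correlations whose sign agrees with the truth.
#' Component `i` of the estimate (output order, decreasing magnitude) is
#' compared with the true sign at position `i`; the minimal-rotation sign
#' convention of [svd_signed()] makes this positional pairing consistent
#' even though the true magnitudes are all equal. Correct signs are pooled
#' over components and replicates within each cell.
#'
#' @param n_grid integer vector of sample sizes.
#' @param lam_grid numeric vector of correlation strengths in (0, 1).
#' @param reps replicates per cell (500 in the reference design; reduce for
#'   quick checks).
#' @param p,q dimensions (defaults 60 and 10).
#' @param seed integer base seed; each (cell, replicate) combination uses a
#'   deterministic substream so results are reproducible and cells are
#'   independent.
#' @param detail if `TRUE`, also return the per-replicate, per-component
#'   long table.
#'
#' @return a data frame with columns `n`, `lambda`, `proportion`, `reps`,
#'   `seed` (one row per grid cell). With `detail = TRUE`, a list with
#'   elements `summary` (that data frame) and `detail` (columns `n`,
#'   `lambda`, `rep`, `component`, `true_sign`, `est_lambda`).
#' @export
sign_recovery_experiment <- function(n_grid, lam_grid, reps = 500,
                                     p = 60, q = 10, seed = 1,
                                     detail = FALSE) {
  if (length(n_grid) == 0 || length(lam_grid) == 0) {
    stop("'n_grid' and 'lam_grid' must be nonempty")
  }
  if (reps < 1) stop("'reps' must be at least 1")
  m <- min(p, q)
  cells <- expand.grid(n = n_grid, lambda = lam_grid,
                       KEEP.OUT.ATTRS = FALSE)
  summary_rows <- vector("list", nrow(cells))
  detail_rows <- if (detail) vector("list", nrow(cells)) else NULL
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; lam <- cells$lambda[ci]
    truth_sign <- rep_len(c(1, -1), m)
    cell_seed <- (seed + 7919L * (ci - 1L)) %% .Machine$integer.max
    sims <- simulate_synthetic_design(n, lam, reps = reps, p = p, q = q,
                                      seed = cell_seed)
    est <- vapply(sims, function(d) {
      cca_fit(d$X, d$Y, estimator = "shrinkage")$lambda
    }, numeric(m))                     # m x reps
    correct <- sweep(sign(est), 1, truth_sign, "==")
    summary_rows[[ci]] <- data.frame(n = n, lambda = lam,
                                     proportion = mean(correct),
                                     reps = reps, seed = seed)
    if (detail) {
      detail_rows[[ci]] <- data.frame(
        n = n, lambda = lam,
        rep = rep(seq_len(reps), each = m),
        component = rep(seq_len(m), times = reps),
        true_sign = rep(truth_sign, times = reps),
        est_lambda = as.vector(est))
    }
  }
  summ <- do.call(rbind, summary_rows)
  if (detail) list(summary = summ, detail = do.call(rbind, detail_rows))
  else summ
}
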