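#' Read a delimited sample-by-variable table
#'
#' Reads a CSV or TSV file whose header names the variables and whose first
#' column holds unique sample identifiers. All remaining cells must be
#' decimal numerics; missing or blank cells are rejected outright — no
#' imputation is attempted, because silently filled values would corrupt
#' the correlation estimates downstream.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` (default) chooses `"\t"` for
#'   `.tsv`/`.txt` files and `","` otherwise.
#'
#' @return numeric matrix with sample identifiers as row names and variable
#'   names as column names.
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("table must have a sample-id column and at least one variable")
  ids <- tab[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sample identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  blank <- vals == "" | toupper(vals) == "NA"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(blank | is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric or missing cell at row '", ids[bad[1, 1]],
         "', column '", colnames(vals)[bad[1, 2]], "'")
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a sample-by-variable matrix as a delimited table
#'
#' Inverse of [read_matrix()]: writes the row names as a leading
#' `sample_id` column. Numbers are written with 12 significant digits so
#' that a write/read round trip and determinism checks are meaningful.
#'
#' @param x numeric matrix with row names.
#' @param path output file path.
#' @param delimiter field separator; `NULL` picks it from the extension as
#'   in [read_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = NULL) {
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  df <- data.frame(sample_id = rownames(x),
                   signif(x, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Align two tables on their sample identifiers
#'
#' Inner join on row names, preserving the row order of `X`. Samples present
#' in only one table are dropped (with a message stating how many were
#' dropped from each side). Fewer than 3 common samples is an error, since
#' no covariance can be usefully estimated below that.
#'
#' @param X,Y numeric matrices with sample identifiers as row names.
#' @return list with the aligned matrices `X` and `Y`.
#' @export
align_samples <- function(X, Y) {
  if (is.null(rownames(X)) || is.null(rownames(Y))) {
    stop("both tables need sample identifiers as row names")
  }
  common <- rownames(X)[rownames(X) %in% rownames(Y)]
  if (length(common) < 3) {
    stop("only ", length(common),
         " common sample(s); at least 3 matched samples are required")
  }
  drop_x <- nrow(X) - length(common)
  drop_y <- nrow(Y) - length(common)
  if (drop_x + drop_y > 0) {
    message("align_samples: dropped ", drop_x, " sample(s) from X and ",
            drop_y, " from Y; ", length(common), " matched samples retained")
  }
  list(X = X[common, , drop = FALSE], Y = Y[common, , drop = FALSE])
}

#' Validate an analysis configuration
#'
#' Checks a configuration list for the `fit` command before any computation
#' touches the data: unknown keys are rejected, defaults are filled in.
#'
#' @param config named list; recognized keys are `x`, `y` (input paths),
#'   `out` (output directory), `estimator` (`"auto"`, `"empirical"`,
#'   `"shrinkage"`), `standardize` (logical), `lambda_shrink` (numeric
#'   override or `"auto"`), `delimiter`, `seed` (integer), `nonnegative`
#'   (logical), `verbose` (logical).
#'
#' @return validated configuration list with defaults applied.
#' @export
analysis_config <- function(config) {
  defaults <- list(x = NULL, y = NULL, out = "cca_out",
                   estimator = "auto", standardize = TRUE,
                   lambda_shrink = "auto", delimiter = NULL,
                   seed = 1L, nonnegative = FALSE, verbose = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$x) || is.null(cfg$y)) {
    stop("configuration must provide both input paths 'x' and 'y'")
  }
  if (!cfg$estimator %in% c("auto", "empirical", "shrinkage")) {
    stop("'estimator' must be one of auto, empirical, shrinkage")
  }
  if (!identical(cfg$lambda_shrink, "auto")) {
    cfg$lambda_shrink <- as.numeric(cfg$lambda_shrink)
    if (is.na(cfg$lambda_shrink) || cfg$lambda_shrink <= 0 ||
        cfg$lambda_shrink > 1) {
      stop("'lambda_shrink' must be in (0, 1] or \"auto\"")
    }
  }
  cfg$standardize <- isTRUE(as.logical(cfg$standardize))
  cfg$nonnegative <- isTRUE(as.logical(cfg$nonnegative))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# write one numeric matrix of the output bundle (12 significant digits)
write_bundle_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the two-table CCA analysis end to end
#'
#' Reads the two tables, aligns the samples, fits the CCA model and writes
#' the output bundle into the configured directory:
#' `canonical_correlations.tsv` (component, signed lambda, lambda squared,
#' cumulative share of the predictive MSE reduction),
#' `directions_X.tsv` / `directions_Y.tsv` (canonical direction vectors,
#' one row per component), `scores_X.tsv` / `scores_Y.tsv`,
#' `correlation_loadings_X.tsv` / `correlation_loadings_Y.tsv` (with the
#' squared loadings appended, the quantity usually plotted to judge which
#' observed variables drive each component), and `run_info.json`.
#'
#' With `nonnegative = TRUE` the reported correlations are `|lambda|` and
#' each negative sign is absorbed into the corresponding Y-side direction
#' and loadings rows, matching the classical convention.
#'
#' @param config list accepted by [analysis_config()].
#'
#' @return the fitted `"cca"` model, invisibly; side effect is the written
#'   bundle.
#' @export
run_cca_command <- function(config) {
  cfg <- analysis_config(config)
  set.seed(cfg$seed)
  X <- read_matrix(cfg$x, cfg$delimiter)
  Y <- read_matrix(cfg$y, cfg$delimiter)
  ali <- align_samples(X, Y)
  fit <- cca_fit(ali$X, ali$Y, estimator = cfg$estimator,
                 lambda_shrink = cfg$lambda_shrink,
                 standardize = cfg$standardize)
  sc <- cca_scores(fit, ali$X, ali$Y)

  lam <- fit$lambda
  W_Y <- fit$W_Y; Psi_Y <- fit$Psi_Y; Q_Y <- fit$Q_Y
  score_Y <- sc$Y
  if (cfg$nonnegative) {
    s <- sign_or_one(lam)
    lam <- abs(lam)
    W_Y <- W_Y * s; Psi_Y <- Psi_Y * s; Q_Y <- Q_Y * s
    score_Y <- sweep(score_Y, 2, s, "*")
  }

  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out, f)
  imp <- lam^2
  write_bundle_table(
    data.frame(component = seq_along(lam), lambda = lam,
               lambda_squared = imp,
               cumulative_delta_share = cumsum(imp) / sum(imp)),
    pth("canonical_correlations.tsv"))
  dir_df <- function(M) {
    data.frame(component = seq_len(nrow(M)), M, check.names = FALSE)
  }
  colnames(fit$W_X) <- colnames(ali$X); colnames(W_Y) <- colnames(ali$Y)
  colnames(fit$Psi_X) <- colnames(ali$X); colnames(Psi_Y) <- colnames(ali$Y)
  write_bundle_table(dir_df(fit$W_X), pth("directions_X.tsv"))
  write_bundle_table(dir_df(W_Y), pth("directions_Y.tsv"))
  loadings_df <- function(Psi) {
    sq <- Psi^2
    colnames(sq) <- paste0(colnames(Psi), ".squared")
    data.frame(component = seq_len(nrow(Psi)), Psi, sq, check.names = FALSE)
  }
  write_bundle_table(loadings_df(fit$Psi_X), pth("correlation_loadings_X.tsv"))
  write_bundle_table(loadings_df(Psi_Y), pth("correlation_loadings_Y.tsv"))
  score_df <- function(S) {
    data.frame(sample_id = rownames(ali$X),
               matrix(S, nrow(S), ncol(S),
                      dimnames = list(NULL, paste0("CC", seq_len(ncol(S))))),
               check.names = FALSE)
  }
  write_bundle_table(score_df(sc$X), pth("scores_X.tsv"))
  write_bundle_table(score_df(score_Y), pth("scores_Y.tsv"))
  info <- list(package = "whitecca",
               version = as.character(utils::packageVersion("whitecca")),
               estimator = fit$meta$estimator,
               shrinkage_intensity = fit$meta$lambda_shrink,
               standardize = cfg$standardize,
               nonnegative = cfg$nonnegative,
               n = nrow(ali$X), p = ncol(ali$X), q = ncol(ali$Y),
               m = fit$m, seed = cfg$seed)
  jsonlite::write_json(info, pth("run_info.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(fit)
}
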