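#' Fit an elastic-net linear regression by coordinate descent
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\left[\frac{1-\alpha}{2}\lVert\beta\rVert_2^2 +
#'   \alpha\lVert\beta\rVert_1\right]}
#' with an unpenalized intercept, via cyclic coordinate descent with
#' active-set iteration (compiled). `alpha = 1` is the lasso, `alpha = 0`
#' ridge regression. Features are *not* variance-standardized by default:
#' methylation values share a natural \[0, 1\] scale (set
#' `standardize = TRUE` to standardize internally; coefficients are
#' returned on the original scale either way).
#'
#' @param X Numeric matrix, n samples by p features (no missing values).
#' @param y Numeric response of length n.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param lambda Penalty strength (single non-negative number).
#' @param standardize Standardize columns to unit variance internally?
#'   Default `FALSE`.
#' @param tol Convergence tolerance on the maximum weighted squared
#'   coefficient change per sweep (default 1e-12).
#' @param max_iter Maximum coordinate-descent sweeps (default 1e5).
#' @return A list with `intercept`, `beta` (length p, named if `X` has
#'   column names), `alpha`, `lambda`, `iterations`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, standardize = FALSE,
                            tol = 1e-12, max_iter = 1e5) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) abort("non-finite values in X or y")
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, ncol(X) >= 1,
            alpha >= 0, alpha <= 1, all(lambda >= 0))
  lambda_path <- sort(unique(lambda), decreasing = TRUE)
  fit <- enet_path_fit(X, y, alpha, lambda_path, standardize, tol, max_iter)
  l <- length(lambda_path)  # the requested (smallest) lambda, warm-started
  list(intercept = fit$intercept[l], beta = fit$beta[, l],
       alpha = alpha, lambda = fit$lambda[l],
       iterations = fit$iterations[l])
}

# Path version with warm starts; lambda must be decreasing.
enet_path_fit <- function(X, y, alpha, lambda, standardize = FALSE,
                          tol = 1e-12, max_iter = 1e5) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm, "-")
  scale_ <- rep(1, ncol(X))
  if (standardize) {
    scale_ <- sqrt(colSums(Xc^2) / n)
    scale_[scale_ == 0] <- 1
    Xc <- sweep(Xc, 2, scale_, "/")
  }
  ym <- mean(y)
  yc <- y - ym
  res <- enet_cd_path(Xc, yc, alpha, lambda, tol, as.integer(max_iter))
  beta <- res$beta / scale_
  rownames(beta) <- colnames(X)
  intercept <- ym - drop(crossprod(xm, beta))
  list(intercept = intercept, beta = beta, lambda = lambda,
       alpha = alpha, iterations = res$iterations)
}

#' Elastic-net objective value
#'
#' The penalized least-squares criterion minimized by
#' [fit_elastic_net()]; exposed for optimality checking.
#'
#' @inheritParams fit_elastic_net
#' @param intercept,beta Candidate solution.
#' @return The objective value (a number).
#' @export
elastic_net_objective <- function(X, y, intercept, beta, alpha, lambda) {
  n <- nrow(X)
  r <- y - intercept - drop(as.matrix(X) %*% beta)
  sum(r^2) / (2 * n) +
    lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

#' Default penalty grid for the elastic net
#'
#' Log-spaced sequence below the smallest lambda that zeroes every
#' coefficient (computed on centered data), with the denser-than-samples
#' regime using a larger floor.
#'
#' @inheritParams fit_elastic_net
#' @param nlambda Number of grid points (default 60).
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest
#'   (default 1e-2 when p > n, else 1e-4).
#' @return A decreasing numeric vector of penalties.
#' @export
default_lambda_grid <- function(X, y, alpha, nlambda = 60,
                                lambda_min_ratio = NULL) {
  n <- nrow(X)
  Xc <- sweep(as.matrix(X), 2, colMeans(X), "-")
  yc <- y - mean(y)
  lambda_max <- max(abs(crossprod(Xc, yc))) / (n * max(alpha, 1e-3))
  if (lambda_max <= 0) lambda_max <- 1
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (n < ncol(X)) 1e-2 else 1e-4
  }
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

#' Select the elastic-net penalty by k-fold cross-validation
#'
#' Splits samples into `k_folds` seeded folds, fits the full lambda path on
#' each training split with warm starts, and scores each lambda by the mean
#' over folds of the out-of-fold RMSE. The selected lambda minimizes that
#' curve; ties are broken toward the larger (sparser) lambda. With
#' `one_se = TRUE` the largest lambda within one standard error of the
#' minimum is chosen instead.
#'
#' @inheritParams fit_elastic_net
#' @param lambda_grid Candidate penalties (default: data-derived log grid).
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param one_se Use the one-standard-error rule? Default `FALSE`.
#' @param fold_id Optional explicit fold assignment (length n), overriding
#'   the seeded split.
#' @return A list: `lambda` (selected), `cv_curve` (tibble with `lambda`,
#'   `rmse`, `se`), `fold_id`.
#' @export
select_lambda_cv <- function(X, y, alpha, lambda_grid = NULL, k_folds = 10,
                             seed = 1L, one_se = FALSE, standardize = FALSE,
                             fold_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k_folds >= 2, n >= k_folds)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y, alpha)
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  if (is.null(fold_id)) {
    fold_id <- withr::with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  }
  rmse_fold <- matrix(NA_real_, nrow = k_folds, ncol = length(lambda_grid))
  for (k in seq_len(k_folds)) {
    tr <- fold_id != k
    fit <- enet_path_fit(X[tr, , drop = FALSE], y[tr], alpha, lambda_grid,
                         standardize = standardize)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2, fit$intercept, "+")
    rmse_fold[k, ] <- sqrt(colMeans((pred - y[!tr])^2))
  }
  mean_rmse <- colMeans(rmse_fold)
  se_rmse <- apply(rmse_fold, 2, sd) / sqrt(k_folds)
  best <- min(mean_rmse)
  idx <- which(mean_rmse == best)[1]  # grid is decreasing: first = largest lambda
  if (one_se) {
    idx <- which(mean_rmse <= best + se_rmse[idx])[1]
  }
  list(lambda = lambda_grid[idx],
       cv_curve = tibble::tibble(lambda = lambda_grid, rmse = mean_rmse,
                                 se = se_rmse),
       fold_id = fold_id)
}
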