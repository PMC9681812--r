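# Ridge regression via the SVD of the (centered) design matrix:
# deterministic, exact, and cheap to evaluate along a whole penalty grid.

#' Fit a ridge regression model
#'
#' Minimizes `sum((y - b0 - X b)^2) + lambda * sum(b^2)` with the
#' intercept unpenalized. The solution is computed from the singular value
#' decomposition of the column-centered design, so it is deterministic,
#' exact at `lambda = 0` (reducing to least squares on well-conditioned
#' designs, the minimum-norm solution otherwise), and shrinks smoothly to
#' the intercept-only model as `lambda` grows.
#'
#' @param X Numeric matrix (rows = subjects, columns = features; typically
#'   the standardized output of [standardize()]).
#' @param y Numeric response aligned with the rows of `X`.
#' @param lambda Non-negative ridge penalty.
#' @param intercept Include an unpenalized intercept (default `TRUE`).
#' @return A `ridge_fit`: list with `coefficients` (named), `intercept`,
#'   `lambda`, and the column names of the training design.
#' @examples
#' X <- matrix(c(1, -1), ncol = 1)
#' fit_ridge(X, c(1, -1), lambda = 2, intercept = FALSE)$coefficients  # 0.5
#' @export
fit_ridge <- function(X, y, lambda, intercept = TRUE) {
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X)
  if (n < 2L || length(y) != n)
    stop_gaitprog("gaitprog_domain_error",
                  "need n >= 2 rows of X aligned with y (n = %d, length(y) = %d)",
                  n, length(y))
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_gaitprog("gaitprog_domain_error", "non-finite values in X or y")
  if (!is.finite(lambda) || lambda < 0)
    stop_gaitprog("gaitprog_domain_error", "lambda must be >= 0")

  dec <- ridge_decompose(X, intercept)
  beta <- ridge_solve(dec, y, lambda)
  b0 <- if (intercept) mean(y) - sum(dec$xbar * beta) else 0
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 intercept = b0, lambda = lambda,
                 feature_names = colnames(X), has_intercept = intercept),
            class = "ridge_fit")
}

# SVD of the (optionally centered) design; reused across a lambda path
ridge_decompose <- function(X, intercept = TRUE) {
  xbar <- if (intercept) colMeans(X) else rep(0, ncol(X))
  Xc <- if (intercept) sweep(X, 2L, xbar, "-") else X
  sv <- svd(Xc)
  list(u = sv$u, d = sv$d, v = sv$v, xbar = xbar, intercept = intercept)
}

ridge_solve <- function(dec, y, lambda) {
  yc <- if (dec$intercept) y - mean(y) else y
  uty <- crossprod(dec$u, yc)
  d <- dec$d
  shrink <- ifelse(d > max(d[1], 0) * 1e-12,
                   d / (d^2 + lambda), 0)  # null directions get 0
  drop(dec$v %*% (shrink * uty))
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("<ridge_fit> p = %d, lambda = %.4g, intercept = %.4g\n",
              length(x$coefficients), x$lambda, x$intercept))
  invisible(x)
}

#' Predict from a ridge fit
#'
#' @param object A `ridge_fit`.
#' @param newdata Numeric matrix whose columns match the training design.
#' @param ... Unused.
#' @return Numeric vector `intercept + newdata %*% coefficients`.
#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_names))
    stop_gaitprog("gaitprog_format_error",
                  "newdata columns do not match the fitted model")
  drop(object$intercept + newdata %*% object$coefficients)
}

#' Default ridge penalty grid
#'
#' Log-spaced grid used by [select_penalty()] in auto mode.
#'
#' @param n_points Grid size.
#' @param min,max Grid endpoints (positive).
#' @return Increasing numeric vector.
#' @export
lambda_grid <- function(n_points = 50L, min = 1e-2, max = 1e6) {
  stopifnot(n_points >= 1L, min > 0, max >= min)
  10^seq(log10(min), log10(max), length.out = n_points)
}

#' Select the ridge penalty by inner cross-validation
#'
#' Chooses the penalty minimizing k-fold cross-validated squared
#' prediction error over a grid, using only the rows supplied -- inside
#' the outer cross-validation this is the training fold, so the held-out
#' fold never influences the penalty. Ties are broken towards the largest
#' (most conservative) penalty.
#'
#' @param X,y Training design and response.
#' @param grid Positive candidate penalties (default [lambda_grid()]).
#' @param k_inner Number of inner folds (default 5; capped at n).
#' @param seed Integer seed for the inner fold assignment.
#' @param intercept Passed to [fit_ridge()].
#' @return List with `lambda` (the selection) and `cv_error` (mean squared
#'   error per grid point).
#' @export
select_penalty <- function(X, y, grid = lambda_grid(), k_inner = 5L,
                           seed = 1L, intercept = TRUE) {
  if (!length(grid) || any(!is.finite(grid)) || any(grid <= 0))
    stop_gaitprog("gaitprog_domain_error",
                  "penalty grid must be non-empty and strictly positive")
  grid <- sort(grid)
  n <- nrow(X)
  if (length(grid) == 1L)
    return(list(lambda = grid, cv_error = NA_real_))
  k_inner <- min(as.integer(k_inner), n)
  folds <- make_folds(n, k_inner, seed = seed)
  sse <- numeric(length(grid))
  for (f in seq_len(k_inner)) {
    tr <- folds != f
    dec <- ridge_decompose(X[tr, , drop = FALSE], intercept)
    ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]
    for (g in seq_along(grid)) {
      beta <- ridge_solve(dec, ytr, grid[g])
      b0 <- if (intercept) mean(ytr) - sum(dec$xbar * beta) else 0
      pred <- drop(b0 + Xte %*% beta)
      sse[g] <- sse[g] + sum((y[!tr] - pred)^2)
    }
  }
  best <- max(which(sse <= min(sse) + 1e-12 * max(min(sse), 1)))
  list(lambda = grid[best], cv_error = sse / n)
}
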