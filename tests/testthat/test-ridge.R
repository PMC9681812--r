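test_that("scalar ridge matches the closed form X'y / (X'X + lambda)", {
  X <- matrix(c(1, -1), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(1, -1)
  for (lam in c(0, 0.5, 2, 10)) {
    fit <- fit_ridge(X, y, lam, intercept = FALSE)
    expect_equal(unname(fit$coefficients), 2 / (2 + lam), tolerance = 1e-12)
  }
})

test_that("lambda = 0 reproduces least squares on well-conditioned designs", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(40)
  fit <- fit_ridge(X, y, 0)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  # fitted values at lambda = 0 match the OLS fit
  expect_equal(predict(fit, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("coefficient norm is non-increasing in lambda; infinite shrinkage", {
  set.seed(4)
  X <- matrix(rnorm(300), 30, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- rnorm(30)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1e4, 1e9),
                  function(l) sqrt(sum(fit_ridge(X, y, l)$coefficients^2)),
                  numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  big <- fit_ridge(X, y, 1e9)
  expect_lt(sqrt(sum(big$coefficients^2)), 1e-5)
  expect_equal(big$intercept, mean(y), tolerance = 1e-4)
})

test_that("ridge agrees with glmnet under the matching parametrization", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 60; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  lam <- 3
  fit <- fit_ridge(X, y, lam)
  # glmnet solves its gaussian path on y scaled by its 1/n standard
  # deviation, so the penalized-RSS lambda maps to lam/n * sd_n(y)
  sdn <- sqrt(var(y) * (n - 1) / n)
  gn <- glmnet::glmnet(X, y, alpha = 0, lambda = lam / n * sdn,
                       standardize = FALSE, intercept = TRUE,
                       thresh = 1e-16, maxit = 1e7)
  expect_equal(unname(fit$coefficients),
               unname(as.numeric(glmnet::coef.glmnet(gn))[-1]),
               tolerance = 1e-5)
})

test_that("ridge rejects degenerate inputs", {
  X <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ridge(X[1, , drop = FALSE], 1, 1),
               class = "gaitprog_domain_error")
  expect_error(fit_ridge(X, c(1, NA), 1), class = "gaitprog_domain_error")
  expect_error(fit_ridge(X, c(1, 2), -1), class = "gaitprog_domain_error")
})

test_that("prediction is affine and column-checked", {
  set.seed(6)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(20)
  fit <- fit_ridge(X, y, 1)
  zeros <- matrix(0, 5, 3, dimnames = list(NULL, paste0("x", 1:3)))
  expect_equal(predict(fit, zeros), rep(fit$intercept, 5))
  X1 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("x", 1:3)))
  X2 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, paste0("x", 1:3)))
  a <- 0.3
  expect_equal(predict(fit, a * X1 + (1 - a) * X2),
               a * predict(fit, X1) + (1 - a) * predict(fit, X2))
  bad <- X1; colnames(bad) <- c("x1", "x2", "zz")
  expect_error(predict(fit, bad), class = "gaitprog_format_error")
})

test_that("penalty selection behaves sensibly at the extremes", {
  expect_equal(select_penalty(matrix(rnorm(20), 10, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              rnorm(10), grid = 7)$lambda, 7)
  expect_error(select_penalty(matrix(rnorm(20), 10, 2), rnorm(10),
                              grid = numeric(0)),
               class = "gaitprog_domain_error")
  expect_error(select_penalty(matrix(rnorm(20), 10, 2), rnorm(10),
                              grid = c(-1, 1)),
               class = "gaitprog_domain_error")

  grid <- lambda_grid(20)
  # pure noise: the selected penalty sits at or near the grid maximum
  set.seed(11)
  noise_picks <- replicate(25, {
    X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
    select_penalty(X, rnorm(50), grid = grid,
                   seed = sample.int(1e6, 1))$lambda
  })
  expect_gt(median(noise_picks), grid[length(grid) - 4L])
  # strong noiseless signal with n >> p: small penalties win
  set.seed(12)
  signal_picks <- replicate(25, {
    X <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
    select_penalty(X, drop(X %*% c(2, -1, 1)), grid = grid,
                   seed = sample.int(1e6, 1))$lambda
  })
  expect_lt(max(signal_picks), grid[4L])
})
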