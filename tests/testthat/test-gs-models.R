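std1n <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

test_that("RR-BLUP equals the closed-form ridge solution at the REML lambda", {
  withr::local_seed(1)
  n <- 8; p <- 3
  X <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X %*% c(1, -0.5, 0.2)) + rnorm(n, 0, 0.5)
  fit <- fit_rrblup(X, y)
  lam <- fit$penalty
  Zc <- scale(X, scale = FALSE)
  s2u <- fit$variance_estimates[["sigma2_u"]]
  s2e <- fit$variance_estimates[["sigma2_e"]]
  V <- s2u * tcrossprod(Zc) + s2e * diag(n)
  Vi <- solve(V); one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  u_closed <- drop(solve(crossprod(Zc) + lam * diag(p), crossprod(Zc, y - mu)))
  expect_equal(unname(fit$effects), unname(u_closed), tolerance = 1e-6)
  # REML lambda agrees with a dense 1-D grid search of the restricted likelihood
  Tb <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1]
  eg <- eigen(crossprod(Tb, tcrossprod(Zc) %*% Tb), symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta2 <- drop(crossprod(Tb %*% eg$vectors, y))^2
  rll <- function(d) -0.5 * ((n - 1) * log(sum(eta2 / (xi + d))) +
                               sum(log(xi + d)))
  grid <- exp(seq(log(lam) - 2, log(lam) + 2, length.out = 8001))
  lam_grid <- grid[which.max(vapply(grid, rll, numeric(1)))]
  expect_equal(lam, lam_grid, tolerance = 1e-3)
})

test_that("RR-BLUP collapses to the null model when the response carries no signal", {
  withr::local_seed(2)
  X <- matrix(rbinom(200, 2, 0.5), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("m", 1:10)))
  y <- rep(5, 20) + rnorm(20, 0, 1e-6)
  fit <- fit_rrblup(X, y)
  expect_lt(max(abs(fit$effects)), 1e-6)
  expect_equal(fit$intercept, mean(y), tolerance = 1e-5)
  expect_error(fit_rrblup(X, rep(1, 20)), "zero-variance")
})

test_that("RR-BLUP recovers a dominant single-marker signal when n > p", {
  withr::local_seed(3)
  X <- matrix(rbinom(50 * 8, 2, 0.5), 50, 8,
              dimnames = list(paste0("s", 1:50), paste0("m", 1:8)))
  y <- 2 * X[, 4]
  fit <- fit_rrblup(X, y)
  expect_equal(which.max(abs(fit$effects)), c(m4 = 4L))
  expect_gt(cor(predict(fit, X), y), 0.999)
})

test_that("the soft-threshold deadzone zeroes a single standardized predictor", {
  withr::local_seed(4)
  n <- 30
  z <- std1n(rnorm(n))
  y <- 0.3 * z + rnorm(n, 0, 0.2)
  Z <- matrix(z, ncol = 1, dimnames = list(paste0("s", 1:n), "m1"))
  lam_star <- abs(sum(z * (y - mean(y)))) / n
  f <- fit_penalized(Z, y, alpha = 1, lambda = lam_star * 1.0001)
  expect_equal(unname(f$effects), 0)
  f2 <- fit_penalized(Z, y, alpha = 1, lambda = lam_star * 0.9)
  expect_gt(abs(f2$effects), 0)
})

test_that("penalized fit at lambda = 0 equals ordinary least squares", {
  withr::local_seed(5)
  n <- 50; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  f <- fit_penalized(X, y, alpha = 1, lambda = 0)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(unname(f$effects), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("single-predictor elastic net matches its closed form", {
  withr::local_seed(6)
  n <- 40
  z <- std1n(rnorm(n))
  y <- 0.8 * z + rnorm(n, 0, 0.3)
  Z <- matrix(z, ncol = 1, dimnames = list(paste0("s", 1:n), "m1"))
  for (lam in c(0.05, 0.2, 0.6)) {
    f <- fit_penalized(Z, y, alpha = 0.5, lambda = lam)
    rho <- sum(z * (y - mean(y))) / n
    b_closed <- sign(rho) * max(0, abs(rho) - lam * 0.5) / (1 + lam * 0.5)
    expect_equal(unname(f$effects), b_closed, tolerance = 1e-8)
  }
})

test_that("coordinate descent agrees with glmnet on the shared objective", {
  skip_if_not_installed("glmnet")
  withr::local_seed(7)
  n <- 40; p <- 60
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X[, 1:5] %*% rnorm(5)) + rnorm(n)
  # glmnet standardizes y internally, which rescales the L2 penalty term;
  # compare on unit-variance y where the two objectives coincide.
  ys <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  for (a in c(1, 0.5)) {
    f <- fit_penalized(X, ys, alpha = a, lambda = 0.1)
    g <- glmnet::glmnet(X, ys, alpha = a, lambda = 0.1, thresh = 1e-14)
    expect_equal(unname(f$effects), as.numeric(stats::coef(g))[-1],
                 tolerance = 1e-5)
  }
})

test_that("elastic net interpolates between ridge and lasso in alpha", {
  withr::local_seed(8)
  n <- 20; p <- 50
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n, 0, 0.5)
  lam <- 0.2
  f_lasso <- fit_penalized(X, y, alpha = 1, lambda = lam)
  f_a1 <- fit_penalized(X, y, alpha = 1 - 1e-9, lambda = lam)
  expect_equal(f_a1$effects, f_lasso$effects, tolerance = 1e-4)
  # alpha -> 0 approaches the closed-form ridge solution
  f_a0 <- fit_penalized(X, y, alpha = 0, lambda = lam)
  st <- scale(X, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  b_ridge <- solve(crossprod(st) / n + lam * diag(p),
                   crossprod(st, y - mean(y)) / n)
  expect_equal(unname(f_a0$effects),
               unname(drop(b_ridge) / attr(st, "scaled:scale")),
               tolerance = 1e-4)
})

test_that("solvers are invariant to adding a constant to the response", {
  withr::local_seed(9)
  n <- 30; p <- 20
  X <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X[, 1:4] %*% rnorm(4)) + rnorm(n)
  for (fitter in list(function(y) fit_rrblup(X, y),
                      function(y) fit_penalized(X, y, alpha = 0.5, lambda = 0.1),
                      function(y) fit_penalized(X, y, alpha = 1, lambda = 0.1))) {
    f1 <- fitter(y); f2 <- fitter(y + 100)
    expect_equal(f1$effects, f2$effects, tolerance = 1e-6)
    expect_equal(f2$intercept - f1$intercept, 100, tolerance = 1e-6)
  }
})

test_that("lasso support shrinks with the penalty and respects the n - 1 bound", {
  withr::local_seed(11)
  n <- 50; p <- 80
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:p)))
  y <- drop(X[, 1:10] %*% rnorm(10)) + rnorm(n)
  Xs <- apply(X, 2, std1n)
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  lams <- exp(seq(log(lam_max * 1.01), log(lam_max * 1e-3), length.out = 25))
  supports <- vapply(lams, function(l)
    sum(fit_penalized(X, y, alpha = 1, lambda = l)$effects != 0), numeric(1))
  expect_equal(supports[1], 0)                      # deadzone above lambda_max
  expect_true(all(supports <= n - 1))               # lasso saturation bound
  # support grows overall as the penalty shrinks (individual entries can
  # leave the active set along the path, so the trend, not each step, is
  # monotone)
  expect_lt(stats::cor(log(lams), supports, method = "spearman"), -0.95)
  expect_gt(supports[25], supports[1])
})

test_that("penalty selection favors heavy shrinkage on pure noise and beats the path ends on signal", {
  nonzero_frac <- vapply(1:10, function(s) {
    X <- rand_dosages(60, 120, seed = 100 + s)
    y <- withr::with_seed(200 + s, rnorm(60))
    names(y) <- rownames(X)
    lam <- select_lambda(X, y, alpha = 1, n_inner_folds = 3, rng_seed = s)
    f <- fit_penalized(X, y, alpha = 1, lambda = as.numeric(lam))
    mean(f$effects != 0)
  }, numeric(1))
  expect_lte(stats::median(nonzero_frac), 0.05)

  X <- rand_dosages(200, 500, seed = 42)
  y <- withr::with_seed(43,
    drop(X[, 1:10] %*% rnorm(10, 0, 1)) + rnorm(200, 0, 1))
  names(y) <- rownames(X)
  lam <- select_lambda(X, y, alpha = 1, n_inner_folds = 5, rng_seed = 7)
  mse <- attr(lam, "cv_mse")
  path <- attr(lam, "path")
  expect_equal(length(path), 100L)
  expect_lte(min(mse), mse[1])
  expect_lte(min(mse), mse[length(mse)])
  expect_lt(mse[which(path == as.numeric(lam))], mse[1])
  expect_lt(mse[which(path == as.numeric(lam))], mse[length(mse)])
})

test_that("penalty selection is deterministic under a fixed seed", {
  X <- rand_dosages(50, 100, seed = 3)
  y <- withr::with_seed(4, rnorm(50)); names(y) <- rownames(X)
  l1 <- select_lambda(X, y, alpha = 0.5, n_inner_folds = 4, rng_seed = 99)
  l2 <- select_lambda(X, y, alpha = 0.5, n_inner_folds = 4, rng_seed = 99)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_identical(attr(l1, "cv_mse"), attr(l2, "cv_mse"))
})

test_that("prediction is linear in dosages and errors on marker mismatch", {
  withr::local_seed(12)
  X <- matrix(rbinom(60, 2, 0.5), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
  y <- drop(X %*% rnorm(6)) + rnorm(10, 0, 0.1)
  fit <- fit_rrblup(X, y)
  X2 <- X; X2[, 3] <- 2 * X[, 3]
  delta <- predict(fit, X2) - predict(fit, X)
  expect_equal(unname(delta), unname(X[, 3] * fit$effects[3]), tolerance = 1e-10)
  # all-zero effects predict the intercept
  f0 <- fit
  f0$effects[] <- 0
  expect_equal(unname(predict(f0, X)), rep(f0$intercept, 10))
  Xbad <- X[, c(2:6, 1)]
  expect_error(predict(fit, Xbad), "mismatch")
})
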