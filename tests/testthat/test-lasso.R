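test_that("objective arithmetic matches hand-computed values", {
  # psi = 0, f = (1, 1): (1/(2*2)) * 2 = 0.5 regardless of L and alpha
  p <- lasso_problem(matrix(c(2, 3), 2, 1), c(1, 1), alpha = 0.7)
  expect_equal(lasso_objective(p, 0), 0.5)
  # N=2, L = (1, -1), f = (1, -1), alpha = 0.5, psi = 0.5 -> 0.375
  p2 <- lasso_problem(matrix(c(1, -1), 2, 1), c(1, -1), alpha = 0.5)
  expect_equal(lasso_objective(p2, 0.5), 0.375)
  # alpha = 0 reduces to half the mean squared residual
  p3 <- lasso_problem(matrix(c(1, -1), 2, 1), c(1, -1), alpha = 0)
  psi <- 0.3
  r <- c(1, -1) - c(1, -1) * psi
  expect_equal(lasso_objective(p3, psi), mean(r^2) / 2)
  expect_error(lasso_objective(p2, c(1, 2)), "length")
})

test_that("1-D closed-form soft-threshold solutions", {
  # standardized column (1, -1), centered response (1, -1)
  p <- lasso_problem(matrix(c(1, -1), 2, 1), c(1, -1), alpha = 0.5)
  fit <- fit_lasso(p)
  expect_equal(fit$psi, 0.5, tolerance = 1e-8)
  expect_true(fit$converged)
  # the reported objective is the recomputed (standardized) objective
  expect_equal(fit$objective,
               lasso_objective(p, fit$psi, standardized = TRUE))
  # alpha = 1 >= alpha_max = 1 -> exact zero
  p1 <- lasso_problem(matrix(c(1, -1), 2, 1), c(1, -1), alpha = 1.0)
  expect_equal(lasso_alpha_max(p1), 1)
  expect_equal(fit_lasso(p1)$psi, 0)
  expect_equal(fit_lasso(p1)$n_nonzero, 0L)
})

test_that("alpha = 0 recovers least squares on a well-conditioned design", {
  set.seed(13)
  L <- matrix(rnorm(30), 10, 3)
  beta <- c(1.5, -2, 0.5)
  f <- as.vector(L %*% beta) + rnorm(10, sd = 0.01)
  p <- lasso_problem(L, f, alpha = 0)
  fit <- fit_lasso(p, tol = 1e-10, max_sweeps = 5000L)
  # normal-equations oracle on the standardized problem
  ols <- solve(crossprod(p$Ls), crossprod(p$Ls, p$fs))
  expect_equal(fit$psi, as.vector(ols), tolerance = 1e-6)
})

test_that("zero-shrinkage threshold annihilates every coefficient", {
  set.seed(17)
  for (rep in 1:5) {
    L <- matrix(rnorm(40), 10, 4)
    f <- rnorm(10)
    p <- lasso_problem(L, f, alpha = 0)
    am <- lasso_alpha_max(p)
    for (a in c(am, 1.5 * am)) {
      pa <- lasso_problem(L, f, alpha = a)
      expect_equal(fit_lasso(pa)$psi, rep(0, 4))
    }
  }
})

test_that("grid-search oracle equivalence for t <= 3", {
  set.seed(19)
  # t = 1 and t = 2 at the spec grid resolution
  for (t in 1:2) {
    L <- matrix(rnorm(8 * t), 8, t)
    f <- rnorm(8)
    p <- lasso_problem(L, f, alpha = 0.2)
    fit <- fit_lasso(p, tol = 1e-9, max_sweeps = 5000L)
    oracle <- grid_search_lasso(p$Ls, p$fs, 0.2, step = 0.01)
    expect_lte(fit$objective, oracle + 1e-4)
  }
  # t = 3 on a 0.02-step grid (same tolerance; pure runtime concession)
  L <- matrix(rnorm(24), 8, 3)
  f <- rnorm(8)
  p <- lasso_problem(L, f, alpha = 0.2)
  fit <- fit_lasso(p, tol = 1e-9, max_sweeps = 5000L)
  oracle <- grid_search_lasso(p$Ls, p$fs, 0.2, step = 0.02)
  expect_lte(fit$objective, oracle + 1e-4)
})

test_that("solver agrees with glmnet on a random problem", {
  skip_if_not_installed("glmnet")
  set.seed(23)
  L <- matrix(rnorm(200), 20, 10)
  f <- as.vector(L %*% c(2, -1, rep(0, 8))) + rnorm(20, sd = 0.5)
  alpha <- 0.1
  p <- lasso_problem(L, f, alpha)
  fit <- fit_lasso(p, tol = 1e-10, max_sweeps = 10000L)
  g <- glmnet::glmnet(p$Ls, p$fs, lambda = alpha, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(fit$psi, as.vector(g$beta), tolerance = 1e-4)
})

test_that("nonzero selection mask and monotone shrinkage in alpha", {
  fit <- structure(list(psi = c(0.5, 0, -0.1)), class = "lasso_fit")
  expect_equal(select_nonzero(fit), c(TRUE, FALSE, TRUE))
  expect_equal(select_nonzero(structure(list(psi = c(0, 0)), class = "lasso_fit")),
               c(FALSE, FALSE))

  # penalty strictly increasing in alpha at fixed psi
  p <- lasso_problem(matrix(rnorm(20), 10, 2), rnorm(10), alpha = 0.1)
  p2 <- lasso_problem(p$L, p$f, alpha = 0.3)
  psi <- c(1, -1)
  expect_gt(lasso_objective(p2, psi), lasso_objective(p, psi))

  # n_nonzero non-increasing from alpha to 10*alpha
  set.seed(29)
  L <- matrix(rnorm(150), 15, 10)
  f <- as.vector(L %*% c(3, -2, 1, rep(0, 7))) + rnorm(15, 0.2)
  n1 <- fit_lasso(lasso_problem(L, f, 0.05))$n_nonzero
  n2 <- fit_lasso(lasso_problem(L, f, 0.5))$n_nonzero
  expect_lte(n2, n1)
})

test_that("a pure-noise column is excluded alongside a true signal column", {
  # signal column standardized (1,-1)-style plus an orthogonal noise column
  L <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  f <- c(1, -1, 1, -1)
  p <- lasso_problem(L, f, alpha = 0.5)
  fit <- fit_lasso(p)
  mask <- select_nonzero(fit)
  expect_true(mask[1])
  expect_false(mask[2])
  # grid oracle confirms the 2-D optimum
  oracle <- grid_search_lasso(p$Ls, p$fs, 0.5, step = 0.01)
  expect_lte(fit$objective, oracle + 1e-4)
})

test_that("constant columns are frozen at zero", {
  L <- cbind(rep(2, 6), rnorm(6))
  f <- rnorm(6)
  p0 <- lasso_problem(L, f, alpha = 0)
  expect_warning(fit <- fit_lasso(p0), "constant")
  expect_equal(fit$psi[1], 0)
  p1 <- lasso_problem(L, f, alpha = 0.1)
  expect_equal(fit_lasso(p1)$psi[1], 0)
})

test_that("multiclass one-hot fits aggregate per the any-nonzero rule", {
  ds <- easy_dataset(seed = 3L)
  fit <- fit_lasso_multiclass(ds, alpha = 0.01)
  expect_equal(dim(fit$psi), c(16L, 4L))
  expect_equal(fit$objective, mean(fit$per_class_objective))
  mask <- select_nonzero(fit)
  expect_equal(mask, apply(fit$psi != 0, 1, any))
  expect_equal(fit$n_nonzero, sum(mask))
})
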