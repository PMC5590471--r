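test_that("regression assembly follows y = -S_E v_E with propagated covariance", {
  pm <- partition_model(toy_model(), toy_measurements())
  prob <- build_regression(pm)
  expect_equal(unname(prob$y), c(-2, -1, 0, 0))
  # hand computation of S_E diag(sd^2) S_E' for the toy (identity-block S_E)
  expect_equal(diag(prob$cov_e)[1:2], c(A = 0.01, B = 0.04))
  expect_equal(prob$cov_e[1, 2], 0)
  # unmeasured rows floored at 1e-6 x smallest nonzero variance
  expect_equal(unname(diag(prob$cov_e)[3:4]), rep(1e-6 * 0.01, 2))
})

test_that("zero measurement sds fall back to an absolute variance floor", {
  meas <- toy_measurements()
  meas$sd <- 0
  pm <- partition_model(toy_model(), meas)
  expect_warning(prob <- build_regression(pm), "floored")
  expect_equal(unname(diag(prob$cov_e)), rep(1e-6, 4))
  # still GLS-fittable thanks to the floor
  expect_s3_class(gls_fit(prob), "flux_estimate")
})

test_that("OLS solves the identity and noiseless designs exactly", {
  y <- c(3, -1, 2)
  est <- ols_fit(make_problem(y, diag(3)))
  expect_equal(unname(est$beta_hat), y)
  expect_equal(est$sse, 0)
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(48), 12, 4)
    beta <- rnorm(4)
    fit <- ols_fit(make_problem(as.numeric(X %*% beta), X))
    expect_lt(max(abs(fit$beta_hat - beta)), 1e-9)
  }
})

test_that("OLS matches the exact rational normal-equations oracle", {
  set.seed(11)
  for (i in 1:8) {
    repeat {
      X <- random_int_matrix(6, 3)
      if (exact_rank(X) == 3) break
    }
    y <- sample(-5:5, 6, replace = TRUE)
    est <- ols_fit(make_problem(y, X))
    expect_equal(unname(est$beta_hat), cramer_normal_equations(X, y),
                 tolerance = 1e-12)
  }
})

test_that("GLS reduces to OLS under spherical errors and obeys whitening equivalence", {
  set.seed(21)
  X <- matrix(rnorm(60), 15, 4)
  y <- as.numeric(X %*% c(1, -1, 2, 0.5) + rnorm(15, 0, 0.3))
  for (c_ in c(0.25, 1, 9)) {
    ge <- gls_fit(make_problem(y, X, c_ * diag(15)))
    oe <- ols_fit(make_problem(y, X))
    expect_equal(ge$beta_hat, oe$beta_hat, tolerance = 1e-12)
  }
  # general positive-definite covariance: GLS == OLS on the whitened problem
  A <- matrix(rnorm(225), 15, 15)
  cov_e <- crossprod(A) + diag(15)
  ge <- gls_fit(make_problem(y, X, cov_e))
  U <- chol(cov_e)
  ow <- ols_fit(make_problem(as.numeric(forwardsolve(t(U), y)),
                             forwardsolve(t(U), X)))
  expect_equal(ge$beta_hat, ow$beta_hat, tolerance = 1e-10)
  expect_equal(ge$sse, ow$sse, tolerance = 1e-10)
  # estimate covariance equals the direct closed form
  direct <- solve(t(X) %*% solve(cov_e) %*% X)
  expect_equal(unname(ge$cov_beta), direct, tolerance = 1e-8)
  # whitened residuals orthogonal to the whitened design
  expect_lt(max(abs(crossprod(forwardsolve(t(U), X), ge$residuals_whitened))), 1e-8)
})

test_that("inflating one measurement's variance removes its influence monotonically", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  beta <- c(2, -1, 0.5, 1)
  y <- as.numeric(X %*% beta)
  y[1] <- y[1] + 5  # corrupt one observation
  ref <- ols_fit(make_problem(y[-1], X[-1, , drop = FALSE]))$beta_hat
  dev <- vapply(c(1e4, 1e8), function(v) {
    cov_e <- diag(10)
    cov_e[1, 1] <- v
    max(abs(gls_fit(make_problem(y, X, cov_e))$beta_hat - ref))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 1e-3)
})

test_that("regression ANOVA uses the uncentered decomposition", {
  # K = 1, N = 3 hand example: y = (1,2,3) on x = (1,1,1):
  # beta = 2, SSE = 2, SST = 14, F = (12/1)/(2/2) = 12; the tabulated 5%
  # point of F(1, 2) is 18.51, so the regression is not significant.
  prob <- make_problem(c(1, 2, 3), matrix(1, 3, 1))
  an <- regression_anova(ols_fit(prob), prob)
  expect_equal(an$f_statistic, 12)
  expect_identical(c(an$df_model, an$df_error), c(1L, 2L))
  expect_false(an$p_value <= 0.05)
  expect_equal(an$p_value, 1 - stats::pf(12, 1, 2))
  # overwhelming signal
  set.seed(5)
  X <- matrix(rnorm(100), 25, 4)
  y <- as.numeric(X %*% c(50, -30, 20, 10) + rnorm(25, 0, 0.01))
  prob2 <- make_problem(y, X)
  expect_lt(regression_anova(ols_fit(prob2), prob2)$p_value, 1e-6)
  # exact fit is flagged
  y3 <- as.numeric(X %*% c(1, 2, 3, 4))
  prob3 <- make_problem(y3, X)
  an3 <- regression_anova(ols_fit(prob3), prob3)
  expect_true(an3$exact_fit)
  expect_identical(an3$p_value, 0)
})

test_that("ANOVA p values are uniform under a pure-noise null", {
  set.seed(99)
  X <- matrix(rnorm(80), 20, 4)
  rej <- mean(replicate(1000, {
    prob <- make_problem(rnorm(20), X)
    regression_anova(ols_fit(prob), prob)$p_value <= 0.05
  }))
  expect_gt(rej, 0.05 - 0.025)
  expect_lt(rej, 0.05 + 0.025)
})
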