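test_that("specification bias vanishes for null or orthogonal omissions", {
  set.seed(13)
  S_I <- matrix(rnorm(20), 5, 4)
  S_O <- matrix(rnorm(5), 5, 1)
  expect_equal(unname(specification_bias(S_I, S_O, 0)$bias), rep(0, 4))
  # omitted column orthogonal to every retained column
  S_I2 <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  S_O2 <- matrix(c(0, 0, 1, -1), 4, 1)
  b <- specification_bias(S_I2, S_O2, 3.7)
  expect_equal(unname(b$bias), c(0, 0))
})

test_that("relative bias summaries exclude undefined (zero-reference) entries", {
  S_I <- cbind(a = c(1, 0, 1), b = c(0, 1, -1))
  S_O <- matrix(c(1, 1, 0), 3, 1)
  b <- specification_bias(S_I, S_O, 2, reference = c(4, 0))
  expect_true(is.na(b$relative["b"]))
  expect_false(anyNA(b$summary))
})

test_that("RESET statistic matches an independent two-fit evaluation on a fixed toy", {
  set.seed(17)
  X <- matrix(rnorm(80), 20, 4)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3) + 0.15 * (X %*% c(1, -2, 0.5, 3))^2 +
                    rnorm(20, 0, 0.3))
  prob <- make_problem(y, X)
  ours <- reset_test(prob, order_p = 1)
  # independent route: two lm() fits and the printed statistic formula
  fit0 <- lm(y ~ X - 1)
  yh <- fitted(fit0)
  fit1 <- lm(y ~ X + I(yh^2) - 1)
  sse0 <- sum(resid(fit0)^2)
  sse1 <- sum(resid(fit1)^2)
  stat <- ((sse0 - sse1) / 1) / (sse1 / (20 - 4 - 1))
  expect_equal(ours$statistic, stat, tolerance = 1e-10)
  expect_identical(ours$df, c(1L, 15L))
  # and against the established implementation
  lt <- lmtest::resettest(fit0, power = 2, type = "fitted")
  expect_equal(ours$statistic, unname(lt$statistic), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(lt$p.value), tolerance = 1e-8)
})

test_that("RESET is zero when the power column carries no residual signal", {
  # construct y = X b + e with e orthogonal to both X and the fitted powers
  set.seed(23)
  X <- matrix(rnorm(30), 15, 2)
  b <- c(1.5, -0.7)
  yhat <- as.numeric(X %*% b)
  basis <- cbind(X, yhat^2, yhat^3)
  e <- rnorm(15)
  e <- e - basis %*% qr.coef(qr(basis), e)  # residualize against X and powers
  prob <- make_problem(yhat + as.numeric(e), X)
  r <- reset_test(prob, order_p = 1)
  expect_lt(r$statistic, 1e-16)
  expect_false(r$reject)
})

test_that("RESET refuses degenerate power columns", {
  # a single constant regressor makes yhat^2 collinear with the design
  prob <- make_problem(c(1, 2, 3, 2, 1, 3), matrix(1, 6, 1))
  expect_error(reset_test(prob, order_p = 1), "collinear")
  prob2 <- make_problem(rnorm(6), matrix(rnorm(24), 6, 4))
  expect_error(reset_test(prob2, order_p = 2), "degrees of freedom")
})

test_that("F-test statistic matches anova() and is invariant to Z recombination", {
  set.seed(29)
  X <- matrix(rnorm(80), 20, 4)
  Z <- matrix(rnorm(40), 20, 2)
  colnames(Z) <- c("z1", "z2")
  y <- as.numeric(X %*% c(1, 2, -1, 0.5) + Z %*% c(0.8, -0.3) + rnorm(20, 0, 0.4))
  prob <- make_problem(y, X)
  ours <- f_test(prob, Z)
  ref <- anova(lm(y ~ X - 1), lm(y ~ X + Z - 1))
  expect_equal(ours$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(ours$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  # column-space invariance: Z -> Z G for invertible G
  G <- matrix(c(2, 1, -1, 3), 2, 2)
  ZG <- Z %*% G
  colnames(ZG) <- colnames(Z)
  expect_equal(f_test(prob, ZG)$statistic, ours$statistic, tolerance = 1e-10)
})

test_that("F-test rejects spanned candidates with a rank error, not statistic 0", {
  set.seed(37)
  X <- matrix(rnorm(60), 15, 4)
  Z <- cbind(dup = X[, 1] + X[, 2])
  expect_error(f_test(make_problem(rnorm(15), X), Z), "dup")
})

test_that("LM statistic matches a scalar hand computation (o = 1)", {
  set.seed(43)
  X <- matrix(rnorm(45), 15, 3)
  z <- matrix(rnorm(15), 15, 1)
  y <- as.numeric(X %*% c(1, -1, 2) + 0.9 * z + rnorm(15, 0, 0.5))
  prob <- make_problem(y, X)
  ours <- lm_test(prob, z)
  # independent scalar route with explicit inversions
  Xb <- cbind(1, X)
  zc <- as.numeric(z - Xb %*% solve(t(Xb) %*% Xb, t(Xb) %*% z))
  e <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  NKo <- (15 - 3) / (15 - 3 - 1)
  stat <- sum(zc * e)^2 / (NKo * sum(zc^2 * e^2))
  expect_equal(ours$statistic, stat, tolerance = 1e-10)
  expect_identical(ours$df, 1L)
  expect_equal(ours$critical_value, qchisq(0.95, 1))
})

test_that("LM statistic is exactly zero when candidates are orthogonal to residuals", {
  set.seed(47)
  X <- matrix(rnorm(36), 12, 3)
  Z <- matrix(rnorm(24), 12, 2)
  Xb <- cbind(1, X)
  Zc <- Z - Xb %*% qr.coef(qr(Xb), Z)
  e <- rnorm(12)
  e <- e - cbind(X, Zc) %*% qr.coef(qr(cbind(X, Zc)), e)
  y <- as.numeric(X %*% c(1, 2, 3) + e)
  r <- lm_test(make_problem(y, X), Z)
  expect_lt(r$statistic, 1e-18)
  expect_false(r$reject)
})

test_that("test decisions are invariant to a common rescaling of y and X", {
  ds <- small_scenario(seed = 6, cov = 0.05, n_O = 2)
  prob <- make_problem(ds$sim$y, ds$X)
  for (c_ in c(0.01, 100)) {
    probc <- make_problem(c_ * ds$sim$y, c_ * ds$X)
    expect_equal(reset_test(probc, 1)$statistic, reset_test(prob, 1)$statistic,
                 tolerance = 1e-8)
    expect_equal(f_test(probc, ds$S_O)$statistic, f_test(prob, ds$S_O)$statistic,
                 tolerance = 1e-8)
    expect_equal(lm_test(probc, ds$S_O)$statistic, lm_test(prob, ds$S_O)$statistic,
                 tolerance = 1e-8)
  }
})

test_that("reported decisions are internally consistent", {
  ds <- small_scenario(seed = 8, cov = 0.05, n_O = 2)
  prob <- make_problem(ds$sim$y, ds$X)
  for (r in list(reset_test(prob, 1), f_test(prob, ds$S_O),
                 lm_test(prob, ds$S_O), f_test(prob, ds$Z_decoy))) {
    expect_identical(r$reject, r$p_value <= r$alpha)
    if (inherits(r, "mfa_test") && length(r$df) == 2) {
      expect_identical(r$reject, r$statistic >= r$critical_value)
    }
  }
})
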