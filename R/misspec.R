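# Specification bias for omitted reactions and the three misspecification
# tests (RESET, nested F, heteroscedasticity-consistent LM).

#' Specification bias caused by omitted reactions
#'
#' If the true balance is `S_E v_E + S_I v_I + S_O v_O = 0` but the fluxes
#' are estimated with `S_I` alone, the OLS estimate is biased by
#' `(S_I' S_I)^{-1} S_I' S_O v_O`.  With a measurement-error covariance the
#' GLS analogue `(S_I' W S_I)^{-1} S_I' W S_O v_O`, `W = Cov(e)^{-1}`, is
#' computed via whitening.  The bias is zero when `v_O = 0` or when the
#' omitted columns are orthogonal to the retained ones (`S_I' S_O = 0`).
#'
#' @param S_I internal stoichiometry used in the (misspecified) fit; full
#'   column rank.
#' @param S_O stoichiometry of the omitted reactions (same metabolite rows).
#' @param v_O fluxes of the omitted reactions.
#' @param cov_e optional measurement-error covariance for the GLS analogue.
#' @param reference optional reference flux vector (one value per `S_I`
#'   column) against which relative bias is reported, in percent.  Entries
#'   with a zero reference are undefined (`NA`) and excluded from the
#'   summary.
#' @return An object of class `bias_result`: `bias` (flux units),
#'   `relative` (percent, `NA` where undefined), and `summary`
#'   (min/median/mean/max of `|relative|`), plus the method used.
#' @export
specification_bias <- function(S_I, S_O, v_O, cov_e = NULL, reference = NULL) {
  S_I <- as.matrix(S_I)
  S_O <- as.matrix(S_O)
  v_O <- as.numeric(v_O)
  if (nrow(S_I) != nrow(S_O)) stop("S_I and S_O must have the same metabolite rows")
  if (ncol(S_O) != length(v_O)) stop("v_O length must match the omitted columns")
  rhs <- as.numeric(S_O %*% v_O)
  method <- "ols"
  A <- S_I
  b <- rhs
  if (!is.null(cov_e)) {
    U <- chol(cov_e)
    A <- whiten_with(U, S_I)
    b <- as.numeric(whiten_with(U, rhs))
    method <- "gls"
  }
  q <- qr(A)
  if (q$rank < ncol(A)) stop("S_I is rank deficient; bias formula undefined")
  bias <- as.numeric(qr.coef(q, b))
  names(bias) <- colnames(S_I)
  relative <- NULL
  summ <- NULL
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != length(bias)) {
      stop("reference must supply one flux per retained reaction")
    }
    relative <- ifelse(reference != 0, 100 * bias / reference, NA_real_)
    names(relative) <- colnames(S_I)
    ar <- abs(relative[!is.na(relative)])
    if (length(ar)) {
      summ <- c(min = min(ar), median = stats::median(ar),
                mean = mean(ar), max = max(ar))
    }
  }
  structure(list(bias = bias, relative = relative, summary = summ,
                 method = method),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("specification bias (%s): max |bias| = %.4g\n",
              toupper(x$method), max(abs(x$bias))))
  if (!is.null(x$summary)) {
    cat(sprintf("  |relative bias| %%: min %.3g, median %.3g, mean %.3g, max %.3g\n",
                x$summary["min"], x$summary["median"],
                x$summary["mean"], x$summary["max"]))
  }
  invisible(x)
}

# Common packaging for the three tests; enforces the consistency
# reject <=> statistic beyond critical value <=> p <= alpha.
new_mfa_test <- function(test, statistic, df, dist = c("f", "chisq"),
                         alpha, strict, candidate_ids = NULL) {
  dist <- match.arg(dist)
  if (dist == "f") {
    critical <- stats::qf(1 - alpha, df[1], df[2])
    p <- stats::pf(statistic, df[1], df[2], lower.tail = FALSE)
  } else {
    critical <- stats::qchisq(1 - alpha, df[1])
    p <- stats::pchisq(statistic, df[1], lower.tail = FALSE)
  }
  reject <- if (alpha <= 0) FALSE else
    if (strict) statistic > critical else statistic >= critical
  structure(list(test = test, statistic = statistic, df = df,
                 critical_value = critical, p_value = p, alpha = alpha,
                 reject = reject, candidate_ids = candidate_ids),
            class = "mfa_test")
}

#' @export
print.mfa_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = (%s), critical = %.4g (alpha = %g), p = %.4g -> %s\n",
              x$test, x$statistic, paste(x$df, collapse = ", "),
              x$critical_value, x$alpha, x$p_value,
              if (x$reject) "REJECT (misspecification indicated)" else "no rejection"))
  invisible(x)
}

# Pull the (optionally whitened) y/X out of a regression problem.
problem_arrays <- function(problem, whiten) {
  stopifnot(inherits(problem, "regression_problem"))
  y <- problem$y
  X <- problem$X
  U <- NULL
  if (whiten) {
    if (is.null(problem$cov_e)) stop("whiten = TRUE needs cov_e on the problem")
    U <- chol(problem$cov_e)
    y <- as.numeric(whiten_with(U, y))
    X <- whiten_with(U, X)
  }
  list(y = y, X = X, U = U)
}

# Whiten a candidate block with the same factor as the problem.
whiten_block <- function(arr, Z) {
  if (is.null(arr$U)) Z else whiten_with(arr$U, Z)
}

#' Ramsey RESET misspecification test
#'
#' Augments the design with elementwise powers of the fitted values
#' (`yhat^2, ..., yhat^(p+1)`) and F-tests their joint contribution: a
#' Taylor-series stand-in for whatever was left out of the model.  Needs no
#' knowledge of the missing reactions.  Fitted values are scaled by
#' `max(|yhat|)` before exponentiation for overflow control; the statistic
#' is unchanged because it depends only on the augmented column space.
#'
#' @param problem a `regression_problem`.
#' @param order_p RESET order `p` (number of power terms; small positive
#'   integer, default 1 = quadratic term only).
#' @param alpha significance level (default 0.05).
#' @param whiten run the test on the whitened (GLS) problem; default is the
#'   raw OLS problem.
#' @return An `mfa_test` with an F reference distribution on
#'   `(p, N - K - p)` degrees of freedom; rejection uses a strict `>` on
#'   the critical value (ties have probability zero).
#' @export
reset_test <- function(problem, order_p = 1, alpha = 0.05, whiten = FALSE) {
  order_p <- as.integer(order_p)
  if (order_p < 1) stop("order_p must be a positive integer")
  arr <- problem_arrays(problem, whiten)
  N <- problem$N
  K <- problem$K
  if (N - K - order_p <= 0) stop("not enough error degrees of freedom for RESET order ", order_p)
  q0 <- qr(arr$X)
  yhat <- as.numeric(qr.fitted(q0, arr$y))
  s <- max(abs(yhat))
  if (s == 0) stop("fitted values are identically zero; RESET power columns are degenerate")
  P <- vapply(seq_len(order_p) + 1L, function(e) (yhat / s)^e, numeric(N))
  Xa <- cbind(arr$X, P)
  if (qr(Xa)$rank < K + order_p) {
    stop("RESET power columns are numerically collinear with the design; try a lower order_p")
  }
  sse0 <- sum(qr.resid(q0, arr$y)^2)
  sse1 <- sum(qr.resid(qr(Xa), arr$y)^2)
  stat <- if (sse1 == 0 && sse0 == 0) 0 else
    max((sse0 - sse1) / order_p, 0) / (sse1 / (N - K - order_p))
  new_mfa_test("RESET", stat, c(order_p, N - K - order_p), "f", alpha,
               strict = TRUE)
}

#' Nested F-test for candidate missing reactions
#'
#' Fits `y = X beta + Z alpha + e` where `Z` holds the stoichiometry of the
#' candidate missing reactions, and tests `H0: alpha = 0` from the drop in
#' the residual sum of squares.  The combined design `[X Z]` must have full
#' column rank.
#'
#' @param problem a `regression_problem`.
#' @param Z candidate block: numeric matrix (metabolite rows matching the
#'   problem) with one column per candidate reaction.
#' @param alpha significance level.
#' @param whiten run on the whitened (GLS) problem.
#' @return An `mfa_test` with reference distribution `F(o, N - K - o)`,
#'   `o = ncol(Z)`; rejection uses `>=` on the critical value.
#' @export
f_test <- function(problem, Z, alpha = 0.05, whiten = FALSE) {
  Z <- as.matrix(Z)
  arr <- problem_arrays(problem, whiten)
  if (nrow(Z) != problem$N) stop("Z must have one row per balance equation")
  N <- problem$N
  K <- problem$K
  o <- ncol(Z)
  if (N - K - o <= 0) stop("not enough error degrees of freedom for ", o, " candidates")
  Zw <- whiten_block(arr, Z)
  check_combined_rank(arr$X, Zw, colnames(Z))
  q0 <- qr(arr$X)
  sse0 <- sum(qr.resid(q0, arr$y)^2)
  sse1 <- sum(qr.resid(qr(cbind(arr$X, Zw)), arr$y)^2)
  stat <- if (sse1 == 0 && sse0 == 0) 0 else
    max((sse0 - sse1) / o, 0) / (sse1 / (N - K - o))
  new_mfa_test("F-test", stat, c(o, N - K - o), "f", alpha,
               strict = FALSE, candidate_ids = colnames(Z))
}

# Full-column-rank check for [X Z]; on failure name the candidate columns
# that are linearly dependent on what precedes them.
check_combined_rank <- function(X, Z, ids = NULL) {
  K <- ncol(X)
  o <- ncol(Z)
  combined <- cbind(X, Z)
  if (check_estimability(combined)$is_estimable) return(invisible(TRUE))
  offenders <- character()
  cur <- X
  r <- svd_rank(cur)$rank
  for (j in seq_len(o)) {
    cand <- cbind(cur, Z[, j])
    rj <- svd_rank(cand)$rank
    if (rj == r) {
      offenders <- c(offenders, ids[j] %||% paste0("candidate ", j))
    } else {
      cur <- cand
      r <- rj
    }
  }
  stop("[X Z] is rank deficient; dependent candidate column(s): ",
       paste(offenders, collapse = ", "))
}

#' Heteroscedasticity-consistent Lagrange multiplier test
#'
#' Score-type test of correlation between the OLS residuals and the part of
#' the candidate block `Z` not explained by the design.  `Z` is
#' residualized against the intercept-augmented design `[1 X]`, giving
#' `Zc`, and the statistic is the quadratic form
#' `e' Zc ((N-K)/(N-K-o) Zc' Omega Zc)^{-1} Zc' e` with
#' `Omega = diag(e_i^2)` built from the base-model OLS residuals (a
#' heteroscedasticity-consistent weighting).  `H0: Zc' e = 0` is rejected
#' against a chi-square with `o` degrees of freedom.
#'
#' @inheritParams f_test
#' @return An `mfa_test` with a chi-square reference distribution on
#'   `o = ncol(Z)` degrees of freedom.
#' @export
lm_test <- function(problem, Z, alpha = 0.05, whiten = FALSE) {
  Z <- as.matrix(Z)
  arr <- problem_arrays(problem, whiten)
  if (nrow(Z) != problem$N) stop("Z must have one row per balance equation")
  N <- problem$N
  K <- problem$K
  o <- ncol(Z)
  if (N - K - o <= 0) stop("not enough error degrees of freedom for ", o, " candidates")
  Zw <- whiten_block(arr, Z)
  Xb <- cbind(1, arr$X)
  qb <- qr(Xb)
  if (qb$rank < ncol(Xb)) stop("[1 X] is rank deficient; LM residualization undefined")
  Zc <- qr.resid(qb, Zw)
  ehat <- as.numeric(qr.resid(qr(arr$X), arr$y))
  fac <- (N - K) / (N - K - o)
  M <- fac * crossprod(Zc, Zc * ehat^2)
  zte <- as.numeric(crossprod(Zc, ehat))
  sol <- tryCatch(solve(M, zte), error = function(e) {
    stop("Zc' Omega Zc is singular: candidates carry no residual-weighted signal")
  })
  stat <- drop(crossprod(zte, sol))
  new_mfa_test("LM", stat, o, "chisq", alpha,
               strict = FALSE, candidate_ids = colnames(Z))
}

#' Export a test result as JSON
#'
#' @param result an `mfa_test`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_test_result <- function(result, path) {
  stopifnot(inherits(result, "mfa_test"))
  out <- list(test_name = result$test, statistic = result$statistic,
              df = as.numeric(result$df), critical_value = result$critical_value,
              p_value = result$p_value, alpha = result$alpha,
              reject = result$reject,
              candidate_ids = result$candidate_ids %||% character())
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
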