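# Ordinary and generalized least-squares flux estimation.
#
# The flux balance S_E v_E + S_I v_I = 0 is rearranged into the regression
# y = X beta + e with y = -S_E v_E, X = S_I and beta = v_I.  There is no
# intercept: y is a balance residual with no natural mean term.

#' Construct a flux regression problem from raw arrays
#'
#' Low-level constructor for callers that already hold the response and
#' design (e.g. simulated balance data); [build_regression()] is the
#' high-level route from a partitioned model.  Checks dimensions, the
#' overdetermination requirement `N >= K`, full column rank of `X`, and
#' symmetry of `cov_e`.
#'
#' @param y length-N response vector (balance residuals, `-S_E v_E`).
#' @param X N x K design matrix (internal stoichiometry).
#' @param cov_e optional N x N measurement-error covariance.
#' @param metabolites,fluxes optional row/column labels (default taken from
#'   the dimnames of `X`).
#' @return A `regression_problem`.
#' @export
regression_problem <- function(y, X, cov_e = NULL,
                               metabolites = NULL, fluxes = NULL) {
  new_regression_problem(y, X, cov_e, metabolites, fluxes)
}

new_regression_problem <- function(y, X, cov_e = NULL,
                                   metabolites = NULL, fluxes = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- length(y)
  K <- ncol(X)
  if (nrow(X) != N) stop("y and X have incompatible dimensions")
  if (N < K) stop("underdetermined problem: fewer balances (", N,
                  ") than unknown fluxes (", K, ")")
  rep_ <- check_estimability(X)
  if (!rep_$is_estimable) {
    stop(sprintf("design matrix X is rank deficient (rank %d of %d columns)",
                 rep_$numerical_rank, rep_$n_columns))
  }
  if (!is.null(cov_e)) {
    cov_e <- as.matrix(cov_e)
    if (!isTRUE(all.equal(cov_e, t(cov_e), tolerance = 1e-8))) {
      stop("cov_e must be symmetric")
    }
  }
  structure(list(y = y, X = X, cov_e = cov_e, N = N, K = K,
                 metabolites = metabolites %||% rownames(X),
                 fluxes = fluxes %||% colnames(X)),
            class = "regression_problem")
}

#' Assemble the flux-estimation regression problem
#'
#' Builds `y = -S_E v_E`, `X = S_I`, and the measurement-error covariance
#' `Cov(e) = S_E diag(sd_E^2) S_E'` propagated from the exchange-flux
#' standard deviations.  Balance rows untouched by any measured exchange
#' have zero propagated variance; to keep one invertible-covariance code
#' path those diagonal entries are floored at `var_floor` times the
#' smallest nonzero propagated variance (an absolute floor of `var_floor`
#' when every sd is zero, with a warning).  The floor approximates treating
#' the unmeasured balances as hard constraints.
#'
#' @param pm a [partition_model()] result.
#' @param var_floor relative variance floor (default `1e-6`).
#' @return An object of class `regression_problem` with elements `y`, `X`,
#'   `cov_e`, `N`, `K` and row/column labels.
#' @export
build_regression <- function(pm, var_floor = 1e-6) {
  stopifnot(inherits(pm, "partitioned_model"))
  y <- as.numeric(-pm$S_E %*% pm$v_E)
  names(y) <- pm$metabolite_ids
  Es <- pm$S_E * rep(pm$sd_E, each = nrow(pm$S_E))  # S_E %*% diag(sd_E)
  cov_e <- tcrossprod(Es)
  d <- diag(cov_e)
  pos <- d > 0
  if (!any(pos)) {
    warning("all measurement sds are zero; covariance floored at ", var_floor)
    floor_val <- var_floor
  } else {
    floor_val <- var_floor * min(d[pos])
  }
  if (!all(pos)) diag(cov_e)[!pos] <- floor_val
  new_regression_problem(y, pm$S_I, cov_e,
                         metabolites = pm$metabolite_ids,
                         fluxes = pm$internal_ids)
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf("regression_problem: N = %d balances, K = %d unknown fluxes%s\n",
              x$N, x$K, if (is.null(x$cov_e)) " (no error covariance: OLS only)" else ""))
  invisible(x)
}

new_flux_estimate <- function(beta, cov_beta, residuals, residuals_w,
                              sse, N, K, method, fluxes) {
  names(beta) <- fluxes
  dimnames(cov_beta) <- list(fluxes, fluxes)
  structure(list(beta_hat = beta, cov_beta = cov_beta,
                 residuals = residuals, residuals_whitened = residuals_w,
                 sse = sse, dof_error = N - K, N = N, K = K, method = method),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("flux_estimate (%s): K = %d fluxes, N = %d balances, SSE = %.6g, dof = %d\n",
              toupper(x$method), x$K, x$N, x$sse, x$dof_error))
  se <- sqrt(diag(x$cov_beta))
  print(utils::head(data.frame(flux = x$beta_hat, se = se), 10))
  if (x$K > 10) cat("...\n")
  invisible(x)
}

#' Ordinary least-squares flux estimate
#'
#' Minimizes `||y - X beta||^2`.  The estimate is computed by QR
#' factorization; it equals the normal-equations solution
#' `(X'X)^{-1} X'y` with covariance `sigma2_hat * (X'X)^{-1}`, where
#' `sigma2_hat = SSE / (N - K)`.
#'
#' @param problem a `regression_problem`.
#' @return A `flux_estimate` with elements `beta_hat`, `cov_beta`,
#'   `residuals`, `sse`, `dof_error`, `method = "ols"`.
#' @export
ols_fit <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  fit <- qr_ls(problem$X, problem$y)
  sigma2 <- fit$sse / (problem$N - problem$K)
  new_flux_estimate(fit$beta, sigma2 * fit$xtx_inv, fit$residuals,
                    fit$residuals, fit$sse, problem$N, problem$K,
                    "ols", problem$fluxes)
}

#' Generalized least-squares flux estimate
#'
#' Minimizes `(y - X beta)' Cov(e)^{-1} (y - X beta)` by whitening with a
#' Cholesky factor `Cov(e) = L L'` and running the OLS path on
#' `L^{-1} y = L^{-1} X beta + L^{-1} e`.  The estimate covariance is
#' `(X' Cov(e)^{-1} X)^{-1}`.
#'
#' @param problem a `regression_problem` with `cov_e` present and positive
#'   definite (see [build_regression()] for the variance floor that
#'   guarantees this for propagated exchange-flux covariances).
#' @return A `flux_estimate`; `residuals` are on the raw scale,
#'   `residuals_whitened` on the whitened scale, and `sse` is the whitened
#'   (GLS) objective value.
#' @export
gls_fit <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  if (is.null(problem$cov_e)) stop("gls_fit needs a measurement-error covariance")
  U <- tryCatch(chol(problem$cov_e),
                error = function(e) stop("cov_e is not positive definite: ",
                                         conditionMessage(e)))
  yw <- as.numeric(whiten_with(U, problem$y))
  Xw <- whiten_with(U, problem$X)
  fit <- qr_ls(Xw, yw)
  res_raw <- problem$y - as.numeric(problem$X %*% fit$beta)
  new_flux_estimate(fit$beta, fit$xtx_inv, res_raw, fit$residuals,
                    fit$sse, problem$N, problem$K, "gls", problem$fluxes)
}

# QR least squares returning everything the estimators need.
qr_ls <- function(X, y) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop(sprintf("estimability error: design matrix has rank %d of %d columns",
                 q$rank, ncol(X)))
  }
  beta <- as.numeric(qr.coef(q, y))
  res <- as.numeric(qr.resid(q, y))
  R <- qr.R(q)
  list(beta = beta, residuals = res, sse = sum(res^2),
       xtx_inv = chol2inv(R))
}

#' Significance of the flux regression (ANOVA)
#'
#' Overall-regression F-test with the uncentered decomposition (the model
#' has no intercept): `SST = y'y`, `SSR = SST - SSE`,
#' `F = (SSR/K) / (SSE/(N-K))`, upper-tail p from `F(K, N-K)`.  For GLS
#' fits the whitened response is used throughout.
#'
#' @param est a `flux_estimate`.
#' @param problem the `regression_problem` it was fitted on.
#' @return An object of class `anova_result` with `f_statistic`,
#'   `df_model`, `df_error`, `p_value` and an `exact_fit` flag (`SSE = 0`
#'   is reported as `p_value = 0`).
#' @export
regression_anova <- function(est, problem) {
  stopifnot(inherits(est, "flux_estimate"), inherits(problem, "regression_problem"))
  y <- problem$y
  if (est$method == "gls") {
    U <- chol(problem$cov_e)
    y <- as.numeric(whiten_with(U, y))
  }
  sst <- sum(y^2)
  sse <- est$sse
  K <- est$K
  dfe <- est$dof_error
  exact <- sse <= .Machine$double.eps^0.75 * max(sst, 1)
  if (exact) {
    f <- Inf
    p <- 0
  } else {
    f <- max((sst - sse) / K, 0) / (sse / dfe)
    p <- stats::pf(f, K, dfe, lower.tail = FALSE)
  }
  structure(list(f_statistic = f, df_model = K, df_error = dfe,
                 p_value = p, exact_fit = exact),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("regression ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_model, x$df_error, x$f_statistic, x$p_value,
              if (x$exact_fit) " (exact fit)" else ""))
  invisible(x)
}

#' Export a flux estimate as JSON
#'
#' Writes per-reaction estimates, standard errors, the residual sum of
#' squares, degrees of freedom, and the ANOVA table.
#'
#' @param est a `flux_estimate`.
#' @param problem the `regression_problem` it came from.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(est, problem, path) {
  an <- regression_anova(est, problem)
  out <- list(
    method = est$method,
    fluxes = data.frame(reaction_id = names(est$beta_hat),
                        estimate = as.numeric(est$beta_hat),
                        se = sqrt(diag(est$cov_beta))),
    sse = est$sse, dof_error = est$dof_error,
    anova = list(f_statistic = an$f_statistic, df_model = an$df_model,
                 df_error = an$df_error, p_value = an$p_value,
                 exact_fit = an$exact_fit))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12, dataframe = "rows")
  invisible(path)
}
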