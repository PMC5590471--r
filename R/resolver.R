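# Iterative repair of a misspecified stoichiometric model: promote
# candidate reactions whose addition significantly improves the flux
# regression.

#' Iteratively repair a model by promoting candidate reactions
#'
#' Given the flux regression for a (possibly misspecified) internal
#' stoichiometry `X` and a matrix of candidate missing reactions, test every
#' k-tuple of the remaining candidates with the nested [f_test()] (or
#' [lm_test()]), and move the passing tuples from the candidate set into the
#' model.  Iterate until no tuple passes; then advance to the next tuple
#' size in `k`.
#'
#' Within an iteration, passing tuples are promoted greedily in descending
#' statistic order (ties broken lexicographically by candidate id), skipping
#' any tuple that overlaps an already-promoted one or whose promotion would
#' break full column rank; all survivors are re-tested against the enlarged
#' model on the next iteration (`promote = "greedy"`).  `promote = "single"`
#' promotes only the top tuple per iteration.  Tuples violating the rank
#' precondition of the test are skipped with a logged notice.
#'
#' @param problem a `regression_problem` built from the reduced model.
#' @param candidates numeric matrix of candidate reactions (metabolite rows
#'   matching the problem, unique column names).
#' @param k tuple-size schedule, e.g. `1` or `c(1, 2)`.  `k = 1` is the
#'   recommended default.
#' @param alpha significance level for promotion.
#' @param test `"f"` (default) or `"lm"`.
#' @param promote `"greedy"` (default) or `"single"`; see Details.
#' @param whiten run the tests on the whitened (GLS) problem.
#' @param max_iterations defensive cap on iterations.
#' @param bonferroni divide `alpha` by the number of tuples tested in the
#'   iteration (off by default; the raw threshold is the documented
#'   behavior).
#' @return An object of class `resolve_state`: `promoted` (data frame of
#'   promoted ids with iteration and statistic), `remaining` (candidate ids
#'   never promoted), `log` (every tested tuple, once per iteration),
#'   `X_final`, and `sse_trace` (non-increasing across promotions).
#' @export
resolve_model <- function(problem, candidates, k = 1, alpha = 0.05,
                          test = c("f", "lm"), promote = c("greedy", "single"),
                          whiten = FALSE, max_iterations = 1000L,
                          bonferroni = FALSE) {
  stopifnot(inherits(problem, "regression_problem"))
  test <- match.arg(test)
  promote <- match.arg(promote)
  candidates <- as.matrix(candidates)
  if (ncol(candidates) > 0 &&
      (is.null(colnames(candidates)) || anyDuplicated(colnames(candidates)))) {
    stop("candidates must have unique column names")
  }
  if (nrow(candidates) != problem$N) stop("candidates must have one row per balance equation")
  test_fun <- if (test == "f") f_test else lm_test

  X_cur <- problem$X
  avail <- sort(colnames(candidates))
  promoted <- list()
  log_rows <- list()
  sse_trace <- numeric()
  iteration <- 0L

  current_sse <- function() {
    sub <- new_regression_problem(problem$y, X_cur, problem$cov_e)
    if (whiten) gls_fit(sub)$sse else ols_fit(sub)$sse
  }
  sse_trace <- current_sse()

  for (kk in as.integer(k)) {
    repeat {
      if (length(avail) < kk) break
      iteration <- iteration + 1L
      if (iteration > max_iterations) {
        stop("resolve_model exceeded max_iterations = ", max_iterations,
             " (promoted so far: ", paste(names(promoted), collapse = ", "), ")")
      }
      sub <- new_regression_problem(problem$y, X_cur, problem$cov_e)
      tuples <- utils::combn(avail, kk, simplify = FALSE)
      level <- if (bonferroni) alpha / length(tuples) else alpha
      results <- vector("list", length(tuples))
      for (i in seq_along(tuples)) {
        tup <- tuples[[i]]
        Z <- candidates[, tup, drop = FALSE]
        rank_ok <- check_estimability(cbind(X_cur, Z))$is_estimable
        if (!rank_ok) {
          results[[i]] <- list(tuple = tup, statistic = NA_real_,
                               p_value = NA_real_, passed = FALSE,
                               note = "skipped: rank precondition violated")
          next
        }
        tr <- test_fun(sub, Z, alpha = level, whiten = whiten)
        results[[i]] <- list(tuple = tup, statistic = tr$statistic,
                             p_value = tr$p_value, passed = tr$reject,
                             note = "")
      }
      passed_idx <- which(vapply(results, function(r) isTRUE(r$passed), logical(1)))
      ord <- passed_idx[order(-vapply(results[passed_idx], `[[`, numeric(1), "statistic"),
                              vapply(results[passed_idx],
                                     function(r) paste(r$tuple, collapse = "|"),
                                     character(1)))]
      actions <- vapply(results, function(r) {
        if (isTRUE(r$passed)) "passed: not promoted" else
          if (nzchar(r$note)) r$note else "not significant"
      }, character(1))
      promoted_now <- character()
      for (i in ord) {
        r <- results[[i]]
        if (promote == "single" && length(promoted_now)) break
        if (length(intersect(r$tuple, promoted_now))) {
          actions[i] <- "skipped: overlaps a promotion this iteration"
          next
        }
        Z <- candidates[, r$tuple, drop = FALSE]
        if (!check_estimability(cbind(X_cur, Z))$is_estimable) {
          actions[i] <- "skipped: promotion would break full column rank"
          next
        }
        X_cur <- cbind(X_cur, Z)
        promoted_now <- c(promoted_now, r$tuple)
        for (id in r$tuple) {
          promoted[[id]] <- data.frame(id = id, k = kk,
                                       iteration = iteration,
                                       statistic = r$statistic,
                                       p_value = r$p_value,
                                       stringsAsFactors = FALSE)
        }
        actions[i] <- "promoted"
      }
      for (i in seq_along(results)) {
        log_rows[[length(log_rows) + 1L]] <-
          result_row(iteration, kk, results[[i]], actions[i])
      }
      if (length(promoted_now) == 0) break
      avail <- setdiff(avail, promoted_now)
      sse_trace <- c(sse_trace, current_sse())
    }
  }

  promoted_df <- if (length(promoted)) {
    do.call(rbind, promoted[order(vapply(promoted, function(d) d$iteration, numeric(1)),
                                  names(promoted))])
  } else {
    data.frame(id = character(), k = integer(), iteration = integer(),
               statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(promoted_df) <- NULL
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iteration = integer(), k = integer(), tuple = character(),
               statistic = numeric(), p_value = numeric(), action = character(),
               stringsAsFactors = FALSE)
  structure(list(promoted = promoted_df, remaining = avail, log = log_df,
                 X_final = X_cur, sse_trace = sse_trace,
                 config = list(k = k, alpha = alpha, test = test,
                               promote = promote, whiten = whiten)),
            class = "resolve_state")
}

result_row <- function(iteration, kk, r, action) {
  data.frame(iteration = iteration, k = kk,
             tuple = paste(r$tuple, collapse = "+"),
             statistic = r$statistic, p_value = r$p_value,
             action = action, stringsAsFactors = FALSE)
}

#' @export
print.resolve_state <- function(x, ...) {
  cat(sprintf("resolve_state: %d candidate(s) promoted, %d remaining, %d iteration(s)\n",
              nrow(x$promoted), length(x$remaining),
              if (nrow(x$log)) max(x$log$iteration) else 0L))
  if (nrow(x$promoted)) print(x$promoted)
  invisible(x)
}

#' Summarize a resolution against known truth
#'
#' @param state a `resolve_state`.
#' @param truth optional list with elements `omitted` (ids of the truly
#'   missing reactions) and `decoys` (ids of candidates absent from the true
#'   network).
#' @return A data frame with per-iteration promotion counts; when `truth`
#'   is given, attributes `remaining_omitted` and `remaining_decoys` hold
#'   the counts of candidates of each provenance never promoted.
#' @export
summarize_resolution <- function(state, truth = NULL) {
  stopifnot(inherits(state, "resolve_state"))
  iters <- if (nrow(state$promoted)) {
    stats::aggregate(id ~ iteration, data = state$promoted, FUN = length)
  } else {
    data.frame(iteration = integer(), id = integer())
  }
  names(iters) <- c("iteration", "n_promoted")
  if (!is.null(truth)) {
    attr(iters, "remaining_omitted") <- length(intersect(state$remaining, truth$omitted))
    attr(iters, "remaining_decoys") <- length(intersect(state$remaining, truth$decoys))
  }
  iters
}

#' Export a resolution as JSON (and optionally the repaired model)
#'
#' @param state a `resolve_state`.
#' @param path output JSON path.
#' @param model_path optional path for the repaired model TSV
#'   (the final design written via [write_flux_model()]).
#' @return `path`, invisibly.
#' @export
write_resolution <- function(state, path, model_path = NULL) {
  stopifnot(inherits(state, "resolve_state"))
  out <- list(promoted = state$promoted, remaining = state$remaining,
              log = state$log, config = state$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "rows")
  if (!is.null(model_path)) {
    write_flux_model(flux_model(state$X_final, allow_orphans = TRUE), model_path)
  }
  invisible(path)
}
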