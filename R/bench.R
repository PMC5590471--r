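# Evaluation harnesses: detection-rate experiments (TP/FN/FP/TN) for the
# three misspecification tests, the bias-vs-ANOVA study, and the resolver
# experiment on synthetic networks.

#' Detection-rate experiment for the misspecification tests
#'
#' For each replicate a fresh random network, null-space flux sample and
#' noisy response are generated.  The true-positive arm applies the test to
#' the reduced design (`n_O` columns randomly removed); for the F and LM
#' tests the candidate block is the truth (the removed columns).  The
#' false-positive arm applies the F/LM test to the reduced design with a
#' distinct, linearly independent decoy block of the same size; the RESET
#' false-positive arm runs on the full (correctly specified) design.  Rates
#' are rejection fractions; by construction `TP + FN = 1` and
#' `FP + TN = 1`.  Tests run on the raw (unwhitened) OLS problem by
#' default.
#'
#' @param m,n_I,m_E,n_O,cov scenario: metabolites, internal reactions,
#'   measured exchange fluxes, omitted reactions, noise CoV.
#' @param tests subset of `c("reset", "f", "lm")`.
#' @param reps replicate count (default 200).
#' @param seed master seed; results are bit-reproducible given the seed.
#' @param alpha significance level.
#' @param reset_order RESET order `p`.
#' @param whiten apply the tests to the whitened (GLS) problem.
#' @param homoscedastic use fixed-sd noise instead of CoV-scaled.
#' @return A data frame with one row per test: scenario columns, `TP`,
#'   `FN`, `FP`, `TN`, `reps`, `seed`.
#' @export
run_detection_experiment <- function(m, n_I, m_E, n_O, cov,
                                     tests = c("reset", "f", "lm"),
                                     reps = 200, seed = 1L, alpha = 0.05,
                                     reset_order = 1, whiten = FALSE,
                                     homoscedastic = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (reps < 1) stop("reps must be >= 1")
  if (n_O < 1) stop("the detection experiment needs at least one omitted reaction")
  hits <- matrix(0L, nrow = length(tests), ncol = 2,
                 dimnames = list(tests, c("tp", "fp")))
  for (r in seq_len(reps)) {
    sr <- derive_seed(seed, paste0("rep", r))
    ds <- simulate_mfa_dataset(m, n_I, m_E, cov, n_O = n_O,
                               decoys = any(tests %in% c("f", "lm")),
                               seed = sr, homoscedastic = homoscedastic)
    prob_red <- new_regression_problem(ds$sim$y, ds$X)
    for (tn in tests) {
      if (tn == "reset") {
        prob_full <- new_regression_problem(ds$sim$y, ds$model$S)
        tp <- reset_test(prob_red, reset_order, alpha, whiten = whiten)$reject
        fp <- reset_test(prob_full, reset_order, alpha, whiten = whiten)$reject
      } else if (tn == "f") {
        tp <- f_test(prob_red, ds$S_O, alpha, whiten = whiten)$reject
        fp <- f_test(prob_red, ds$Z_decoy, alpha, whiten = whiten)$reject
      } else {
        # a singular residual-weighted cross-product leaves the LM statistic
        # undefined; score-type evidence is absent, so count a non-rejection
        lm_try <- function(Z) tryCatch(lm_test(prob_red, Z, alpha,
                                               whiten = whiten)$reject,
                                       error = function(e) FALSE)
        tp <- lm_try(ds$S_O)
        fp <- lm_try(ds$Z_decoy)
      }
      hits[tn, "tp"] <- hits[tn, "tp"] + tp
      hits[tn, "fp"] <- hits[tn, "fp"] + fp
    }
  }
  tp_rate <- hits[, "tp"] / reps
  fp_rate <- hits[, "fp"] / reps
  data.frame(test = tests, m = m, n_I = n_I, m_E = m_E, n_O = n_O, cov = cov,
             TP = tp_rate, FN = 1 - tp_rate, FP = fp_rate, TN = 1 - fp_rate,
             reps = reps, seed = seed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Scenario grid of the random-network detection study
#'
#' The full grid of the benchmark: baseline networks (m = 100, 60 internal,
#' 50 exchange fluxes) with 2/5/10 omitted reactions, small networks
#' (50/30/25) with 2/5/10, and large networks (200/120/100) with 2/5/10/20,
#' each at noise CoV 1, 5, 10 and 20%.
#'
#' @return A data frame with columns `m`, `n_I`, `m_E`, `n_O`, `cov`
#'   (40 scenarios).
#' @export
detection_grid <- function() {
  geom <- rbind(
    expand.grid(m = 100, n_I = 60, m_E = 50, n_O = c(2, 5, 10)),
    expand.grid(m = 50, n_I = 30, m_E = 25, n_O = c(2, 5, 10)),
    expand.grid(m = 200, n_I = 120, m_E = 100, n_O = c(2, 5, 10, 20)))
  grid <- merge(geom, data.frame(cov = c(0.01, 0.05, 0.1, 0.2)))
  grid <- grid[order(grid$m, grid$n_O, grid$cov), ]
  rownames(grid) <- NULL
  grid
}

#' Run the detection experiment over a scenario grid
#'
#' @param grid data frame of scenarios (see [detection_grid()]).
#' @param tests,reps,seed,alpha,... forwarded to
#'   [run_detection_experiment()]; each cell gets a sub-seed derived from
#'   `seed` and its scenario label.
#' @return Row-bound results, one row per (scenario, test).
#' @export
run_detection_grid <- function(grid = detection_grid(), tests = "f",
                               reps = 200, seed = 1L, alpha = 0.05, ...) {
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cell_seed <- derive_seed(seed, sprintf("cell_%d_%d_%d_%g", g$m, g$n_I, g$n_O, g$cov))
    out[[i]] <- run_detection_experiment(g$m, g$n_I, g$m_E, g$n_O, g$cov,
                                         tests = tests, reps = reps,
                                         seed = cell_seed, alpha = alpha, ...)
  }
  do.call(rbind, out)
}

#' Bias and significance-of-regression study for single-reaction omissions
#'
#' For each listed reaction: compute the closed-form specification bias of
#' omitting it (relative to the full-model GLS estimate), then simulate
#' `reps` noisy balance vectors from the full model and record the ANOVA
#' significance of the reduced-model GLS regression.  High mean p values
#' flag a poor regression; the bias summaries show that a significant
#' regression does not guarantee small flux biases.
#'
#' @param model a [flux_model()].
#' @param measurements measurement table (see [read_measurements()]).
#' @param omit_ids internal reactions to omit one at a time; default all
#'   whose removal leaves no orphan metabolite.
#' @param reps simulated data vectors per omission.
#' @param seed master seed.
#' @param var_floor forwarded to [build_regression()].
#' @return A data frame, one row per omitted reaction: the reference flux,
#'   mean and standard error of the ANOVA p value, and the
#'   min/median/mean/max absolute relative bias (percent) over the
#'   remaining fluxes.
#' @export
run_bias_experiment <- function(model, measurements, omit_ids = NULL,
                                reps = 200, seed = 1L, var_floor = 1e-6) {
  pm <- partition_model(model, measurements)
  prob <- build_regression(pm, var_floor)
  ref <- gls_fit(prob)
  vref <- ref$beta_hat
  if (is.null(omit_ids)) {
    omit_ids <- Filter(function(id) {
      !inherits(try(remove_reactions(model, id, forbid_orphans = TRUE),
                    silent = TRUE), "try-error")
    }, pm$internal_ids)
  }
  U <- chol(prob$cov_e)
  y0 <- as.numeric(prob$X %*% vref)
  rows <- lapply(omit_ids, function(id) {
    keep <- setdiff(pm$internal_ids, id)
    X_red <- prob$X[, keep, drop = FALSE]
    b <- specification_bias(X_red, prob$X[, id, drop = FALSE], vref[id],
                            cov_e = prob$cov_e, reference = vref[keep])
    ps <- with_seed(derive_seed(seed, id), {
      vapply(seq_len(reps), function(r) {
        y <- y0 + as.numeric(t(U) %*% stats::rnorm(prob$N))
        sub <- new_regression_problem(y, X_red, prob$cov_e)
        regression_anova(gls_fit(sub), sub)$p_value
      }, numeric(1))
    })
    data.frame(reaction_id = id, flux_ref = unname(vref[id]),
               p_mean = mean(ps), p_se = stats::sd(ps) / sqrt(reps),
               bias_min = b$summary["min"], bias_median = b$summary["median"],
               bias_mean = b$summary["mean"], bias_max = b$summary["max"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resolver experiment on synthetic networks
#'
#' Emulates the resolver benchmark protocol on a synthetic base network:
#' an outer loop draws `S_I_true` by removing `n_extra` random reactions
#' from the base internal stoichiometry (these removed "extra" reactions
#' are decoys never used for data generation); an inner loop samples a true
#' flux vector, simulates noisy data, removes `n_omit` further reactions to
#' form the misspecified working model, pools both removed sets as the
#' candidate matrix, and runs [resolve_model()].  Remaining (never
#' promoted) candidates are counted by provenance; per-generation medians
#' over the inner replicates are averaged over the outer replicates with
#' standard errors.
#'
#' @param m,n_I,m_E base network dimensions (defaults mirror a small
#'   mammalian-cell model: 49 metabolites, 47 internal reactions, 34
#'   measured exchanges).
#' @param n_extra,n_omit candidate-set composition.
#' @param cov noise coefficient of variation.
#' @param k,alpha,promote forwarded to [resolve_model()].
#' @param model_reps,data_reps outer and inner replicate counts.
#' @param seed master seed.
#' @return A list with `remaining_extra` / `remaining_omitted`
#'   (mean, se over outer reps of inner medians), the per-generation
#'   medians, and the configuration.
#' @export
run_resolver_experiment <- function(m = 49, n_I = 47, m_E = 34,
                                    n_extra = 3, n_omit = 3, cov = 0.01,
                                    k = 1, alpha = 0.05, promote = "greedy",
                                    model_reps = 20, data_reps = 5,
                                    seed = 1L) {
  if (n_extra + n_omit >= n_I) stop("n_extra + n_omit must be below n_I")
  base <- random_stoichiometry(m, n_I, m_E, seed = derive_seed(seed, "base"))
  med_extra <- numeric(model_reps)
  med_omit <- numeric(model_reps)
  for (g in seq_len(model_reps)) {
    sg <- derive_seed(seed, paste0("gen", g))
    repeat {
      extra_idx <- with_seed(derive_seed(sg, "extra"),
                             sample.int(n_I, n_extra))
      S_true <- base$S[, -extra_idx, drop = FALSE]
      NE <- S_true[-seq_len(m_E), , drop = FALSE]
      if (svd_rank(S_true)$rank == ncol(S_true) &&
          svd_rank(NE)$rank < ncol(S_true)) break
      sg <- derive_seed(sg, "retry")
    }
    extra_ids <- colnames(base$S)[extra_idx]
    bl <- list(S_E = NULL, S_I = S_true,
               S_I_E = S_true[seq_len(m_E), , drop = FALSE],
               S_I_NE = S_true[-seq_len(m_E), , drop = FALSE],
               m_E = m_E, exchange_ids = paste0("EX_", rownames(S_true)[seq_len(m_E)]))
    v_true <- sample_internal_fluxes(bl$S_I_NE, seed = derive_seed(sg, "fluxes"))
    rem_extra <- integer(data_reps)
    rem_omit <- integer(data_reps)
    for (d in seq_len(data_reps)) {
      sd_seed <- derive_seed(sg, paste0("data", d))
      sim <- simulate_measurements(v_true, bl, cov,
                                   seed = derive_seed(sd_seed, "noise"))
      omit_idx <- with_seed(derive_seed(sd_seed, "omit"),
                            sample.int(ncol(S_true), n_omit))
      omit_ids <- colnames(S_true)[omit_idx]
      X <- S_true[, -omit_idx, drop = FALSE]
      S_A <- cbind(S_true[, omit_idx, drop = FALSE],
                   base$S[, extra_idx, drop = FALSE])
      prob <- new_regression_problem(sim$y, X)
      st <- resolve_model(prob, S_A, k = k, alpha = alpha, promote = promote)
      rem_extra[d] <- length(intersect(st$remaining, extra_ids))
      rem_omit[d] <- length(intersect(st$remaining, omit_ids))
    }
    med_extra[g] <- stats::median(rem_extra)
    med_omit[g] <- stats::median(rem_omit)
  }
  list(remaining_extra = c(mean = mean(med_extra),
                           se = stats::sd(med_extra) / sqrt(model_reps)),
       remaining_omitted = c(mean = mean(med_omit),
                             se = stats::sd(med_omit) / sqrt(model_reps)),
       per_generation = data.frame(generation = seq_len(model_reps),
                                   median_remaining_extra = med_extra,
                                   median_remaining_omitted = med_omit),
       config = list(m = m, n_I = n_I, m_E = m_E, n_extra = n_extra,
                     n_omit = n_omit, cov = cov, k = k, alpha = alpha,
                     model_reps = model_reps, data_reps = data_reps,
                     seed = seed))
}
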