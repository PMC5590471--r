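# Random metabolic network generator and in-silico data engine.
#
# Networks are random full-column-rank stoichiometric matrices in which
# every species participates in at least one reaction; exchange fluxes are
# attached as an identity block on the first m_E metabolites; internal
# fluxes are sampled from the null space of the unmeasured balance block;
# and measurements carry Gaussian noise whose standard deviation scales
# with the noise-free value (a fixed coefficient of variation).

#' Generate a random stoichiometric matrix
#'
#' Each reaction (column) involves 2-4 metabolites with at least one
#' consumed (negative) and one produced (positive), coefficient magnitudes
#' drawn from `magnitudes`.  Every metabolite is guaranteed to participate
#' in at least one reaction, and the matrix is rejection-resampled until it
#' has full column rank.  Generation is a pure function of `seed`.
#'
#' When `m_E > 0` the first `m_E` metabolites are destined to be measured
#' exchange species (see [attach_exchanges()]) and the network is
#' additionally required to be flux-consistent with respect to the
#' unmeasured balances: the null space of the unmeasured-rows block must
#' have no structurally-zero coordinate, i.e. every reaction can carry a
#' nonzero steady-state flux.  Without this requirement, sparse random
#' networks routinely contain reactions whose flux is forced to zero (a
#' metabolite touched by a single reaction pins that reaction, and the
#' zeros cascade), and omitting such a reaction creates no misspecification
#' at all, which would make detection benchmarks degenerate.  To make the
#' rejection sampling practical, unmeasured metabolites are dealt two
#' participation slots each and the leftover slots are steered by the
#' unmeasured-block slack `n_I - (m - m_E)`: a tight block (slack below
#' `n_I / 3`) receives extra participants on unmeasured rows, a loose one
#' spreads them degree-balanced over all rows.  The accepted ensemble is
#' defined by the explicit criteria (rank, coverage, flux support), not by
#' this proposal heuristic.
#'
#' @param m number of metabolites (rows); must satisfy `m >= n_I`
#'   (overdetermined) and `m <= max(participants) * n_I` (coverage feasible).
#' @param n_I number of internal reactions (columns).
#' @param m_E number of metabolites that will carry measured exchange
#'   fluxes (0 disables the flux-consistency requirement).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param participants per-reaction participant count range (default `2:4`).
#' @param magnitudes coefficient magnitude set (default `c(1, 2)`).
#' @param max_attempts rejection bound.
#' @return A [flux_model()] with metabolites `M001...` and reactions
#'   `R001...`.
#' @export
random_stoichiometry <- function(m, n_I, m_E = 0, seed = NULL,
                                 participants = 2:4, magnitudes = c(1, 2),
                                 max_attempts = 100L) {
  if (m < n_I) stop("need m >= n_I for an overdetermined problem")
  if (m > max(participants) * n_I) {
    stop("coverage infeasible: m exceeds max(participants) * n_I; loosen sparsity")
  }
  if (m_E > m) stop("m_E cannot exceed m")
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      S <- sample_stoichiometry_once(m, n_I, m_E, participants, magnitudes)
      if (network_acceptable(S, m_E)) {
        dimnames(S) <- list(sprintf("M%03d", seq_len(m)),
                            sprintf("R%03d", seq_len(n_I)))
        return(flux_model(S))
      }
    }
    stop("failed to draw an acceptable stoichiometric matrix in ", max_attempts,
         " attempts; loosen sparsity or magnitudes")
  })
}

# Rank (+, when m_E > 0, flux-support) acceptance criteria.
network_acceptable <- function(S, m_E) {
  n <- ncol(S)
  if (svd_rank(S)$rank < n) return(FALSE)
  if (m_E <= 0 || m_E >= nrow(S)) return(TRUE)
  NE <- S[(m_E + 1):nrow(S), , drop = FALSE]
  sv <- svd(NE, nu = 0, nv = n)
  tol <- max(dim(NE)) * .Machine$double.eps * max(sv$d)
  rk <- sum(sv$d > tol)
  if (rk >= n) return(FALSE)  # trivial null space: no feasible flux sample
  B <- sv$v[, (rk + 1):n, drop = FALSE]
  all(sqrt(rowSums(B^2)) > 1e-10)
}

sample_stoichiometry_once <- function(m, n_I, m_E, participants, magnitudes) {
  k <- sample(participants, n_I, replace = TRUE)
  need <- if (m_E > 0) 2L * (m - m_E) + m_E else m
  while (sum(k) < need) {
    short <- which(k < max(participants))
    j <- short[sample.int(length(short), 1)]
    k[j] <- k[j] + 1L
  }
  assigned <- vector("list", n_I)
  deg <- integer(m)
  deal <- function(rows) {
    for (r in rows) {
      ok <- which(vapply(seq_len(n_I), function(j) {
        k[j] > length(assigned[[j]]) && !(r %in% assigned[[j]])
      }, logical(1)))
      if (!length(ok)) next
      j <- ok[sample.int(length(ok), 1)]
      assigned[[j]] <<- c(assigned[[j]], r)
      deg[r] <<- deg[r] + 1L
    }
  }
  unmeasured <- if (m_E > 0 && m_E < m) (m_E + 1):m else integer()
  if (length(unmeasured)) {
    deal(sample(unmeasured))
    deal(sample(unmeasured))
    deal(sample(seq_len(m_E)))
  } else {
    deal(sample.int(m))
  }
  tight <- length(unmeasured) > 0 && (n_I - length(unmeasured)) < n_I / 3
  S <- matrix(0, m, n_I)
  for (j in seq_len(n_I)) {
    rows <- assigned[[j]]
    extra <- k[j] - length(rows)
    while (extra > 0) {
      pool <- if (tight) setdiff(unmeasured, rows) else integer()
      if (!length(pool)) pool <- setdiff(seq_len(m), rows)
      if (!tight) {
        dmin <- min(deg[pool])
        pool <- pool[deg[pool] == dmin]
      }
      r <- pool[sample.int(length(pool), 1)]
      rows <- c(rows, r)
      deg[r] <- deg[r] + 1L
      extra <- extra - 1L
    }
    signs <- sample(c(-1, 1), length(rows), replace = TRUE)
    if (all(signs == signs[1])) signs[sample.int(length(signs), 1)] <- -signs[1]
    S[rows, j] <- signs * sample(magnitudes, length(rows), replace = TRUE)
  }
  S
}

#' Attach an identity exchange block to a network
#'
#' The first `m_E` metabolites are designated as measured-exchange species:
#' `S_E = rbind(I_mE, 0)` with one exchange reaction per measured
#' metabolite, and the internal stoichiometry is split row-wise into
#' `S_I_E` (measured rows) and `S_I_NE` (unmeasured rows).
#'
#' @param model a [flux_model()] holding the internal stoichiometry.
#' @param m_E number of measured exchange fluxes; `m_E <= m`.
#' @return A list with `S_E`, `S_I`, `S_I_E`, `S_I_NE`, `m_E` and
#'   `exchange_ids` (named `EX_<metabolite>`).
#' @export
attach_exchanges <- function(model, m_E) {
  stopifnot(inherits(model, "flux_model"))
  m <- nrow(model$S)
  if (m_E > m) stop("m_E cannot exceed the number of metabolites")
  mets <- model$metabolite_ids
  ex_ids <- paste0("EX_", mets[seq_len(m_E)])
  S_E <- rbind(diag(m_E), matrix(0, m - m_E, m_E))
  dimnames(S_E) <- list(mets, ex_ids)
  idx <- seq_len(m_E)
  list(S_E = S_E,
       S_I = model$S,
       S_I_E = model$S[idx, , drop = FALSE],
       S_I_NE = model$S[-idx, , drop = FALSE],
       m_E = m_E,
       exchange_ids = ex_ids)
}

#' Sample internal fluxes from the unmeasured-balance null space
#'
#' Internal fluxes must satisfy the balances of the unmeasured species
#' exactly: `S_I_NE v_I = 0`.  A random flux vector is drawn as
#' `v_I = B c` where `B` is an orthonormal basis of the null space of
#' `S_I_NE` (from the SVD) and `c` has independent Uniform(-1, 1)
#' coordinates.
#'
#' @param S_I_NE unmeasured-rows block of the internal stoichiometry.
#' @param seed integer seed; `NULL` uses the current stream.
#' @param tol singular-value threshold for the null-space split.
#' @return A flux vector (named by reaction if `S_I_NE` has column names)
#'   with `max |S_I_NE v_I| <= 1e-10`.
#' @export
sample_internal_fluxes <- function(S_I_NE, seed = NULL, tol = NULL) {
  S_I_NE <- as.matrix(S_I_NE)
  n <- ncol(S_I_NE)
  sv <- svd(S_I_NE, nu = 0, nv = n)
  if (is.null(tol)) tol <- max(dim(S_I_NE)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank >= n) stop("null space of the unmeasured block is trivial; resample the network")
  B <- sv$v[, (rank + 1L):n, drop = FALSE]
  v <- with_seed(seed, as.numeric(B %*% stats::runif(ncol(B), -1, 1)))
  if (max(abs(S_I_NE %*% v)) > 1e-10) {
    stop("sampled fluxes violate the unmeasured balances beyond tolerance")
  }
  names(v) <- colnames(S_I_NE)
  v
}

#' Simulate noisy balance measurements
#'
#' The noise-free response is `y = S_I v_I`: its first `m_E` entries equal
#' `-v_E` (the measured exchange fluxes, negated) and the remaining entries
#' are exactly zero because `v_I` lies in the unmeasured null space.
#' Gaussian noise with standard deviation `cov * |y_i|` is added to the
#' measured rows only; entries with a zero noise-free value receive no
#' noise (a proportional-noise model, not an additive floor).  With
#' `homoscedastic = TRUE` the measured rows instead share the fixed
#' standard deviation `cov * mean(|y_measured|)`.
#'
#' @param v_I internal flux vector (e.g. from [sample_internal_fluxes()]).
#' @param blocks the block list from [attach_exchanges()].
#' @param cov coefficient of variation of the noise (fraction, `>= 0`).
#' @param seed integer seed; `NULL` uses the current stream.
#' @param homoscedastic use a fixed noise sd instead of CoV-scaled.
#' @return A list: `y` (noisy response), `y0` (noise-free), `v_E`
#'   (noise-free exchange fluxes), `v_E_obs` (their noisy observation),
#'   `sd` (per-measurement noise sd).
#' @export
simulate_measurements <- function(v_I, blocks, cov, seed = NULL,
                                  homoscedastic = FALSE) {
  if (cov < 0) stop("cov must be nonnegative")
  m_E <- blocks$m_E
  y0 <- as.numeric(blocks$S_I %*% v_I)
  y0[-seq_len(m_E)] <- 0  # exact zeros for the unmeasured balances
  sd_vec <- if (homoscedastic) {
    rep(cov * mean(abs(y0[seq_len(m_E)])), m_E)
  } else {
    cov * abs(y0[seq_len(m_E)])
  }
  eps <- with_seed(seed, stats::rnorm(m_E, 0, sd_vec))
  y <- y0
  y[seq_len(m_E)] <- y0[seq_len(m_E)] + eps
  names(y) <- names(y0) <- rownames(blocks$S_I)
  v_E <- -y0[seq_len(m_E)]
  names(v_E) <- blocks$exchange_ids
  list(y = y, y0 = y0, v_E = v_E,
       v_E_obs = stats::setNames(-y[seq_len(m_E)], blocks$exchange_ids),
       sd = stats::setNames(sd_vec, blocks$exchange_ids))
}

#' Remove random reactions to create a misspecified model
#'
#' @param model a [flux_model()] (internal stoichiometry).
#' @param n_remove number of reactions to omit (`< n_I`).
#' @param seed integer seed.
#' @return A list: `reduced` (the retained columns, as a matrix), `S_O`
#'   (the omitted columns), `omitted_ids`, `retained_ids`.  Column removal
#'   preserves full column rank.
#' @export
make_misspecified <- function(model, n_remove, seed = NULL) {
  stopifnot(inherits(model, "flux_model"))
  n <- ncol(model$S)
  if (n_remove >= n) stop("n_remove must be smaller than the number of reactions")
  if (n_remove == 0) {
    return(list(reduced = model$S, S_O = model$S[, 0, drop = FALSE],
                omitted_ids = character(), retained_ids = colnames(model$S)))
  }
  idx <- with_seed(seed, sample.int(n, n_remove))
  list(reduced = model$S[, -idx, drop = FALSE],
       S_O = model$S[, idx, drop = FALSE],
       omitted_ids = colnames(model$S)[idx],
       retained_ids = colnames(model$S)[-idx])
}

#' Draw decoy candidate reactions
#'
#' Samples fresh reaction columns from the same sparsity model as
#' [random_stoichiometry()] (2-4 participants, mixed signs), none equal to
#' an existing column of `X`, such that `[X Z]` has full column rank
#' (rejection-resampled).  Decoys play the false-positive arm of the
#' detection benchmark: candidate reactions absent from the true network.
#'
#' @param X existing design matrix (metabolite rows).
#' @param size number of decoy reactions (`>= 1`).
#' @param seed integer seed.
#' @param participants,magnitudes sparsity model, as in
#'   [random_stoichiometry()].
#' @param max_attempts rejection bound.
#' @return An m x `size` matrix with columns `D001...`.
#' @export
make_decoy_reactions <- function(X, size, seed = NULL, participants = 2:4,
                                 magnitudes = c(1, 2), max_attempts = 100L) {
  X <- as.matrix(X)
  if (size < 1) stop("size must be >= 1")
  m <- nrow(X)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      Z <- matrix(0, m, size)
      for (j in seq_len(size)) {
        kk <- sample(participants, 1)
        rows <- sample.int(m, kk)
        signs <- sample(c(-1, 1), kk, replace = TRUE)
        if (all(signs == signs[1])) signs[sample.int(kk, 1)] <- -signs[1]
        Z[rows, j] <- signs * sample(magnitudes, kk, replace = TRUE)
      }
      dup <- any(apply(Z, 2, function(z) any(colSums(abs(X - z)) == 0)))
      if (!dup && svd_rank(cbind(X, Z))$rank == ncol(X) + size) {
        dimnames(Z) <- list(rownames(X), sprintf("D%03d", seq_len(size)))
        return(Z)
      }
    }
    stop("failed to draw an independent decoy block in ", max_attempts, " attempts")
  })
}

#' Simulate one complete in-silico MFA dataset
#'
#' Orchestrates the generator: random network, exchange block, null-space
#' flux sample, noisy measurements, optional omitted-reaction scenario and
#' decoy candidates.  All randomness flows from `seed` through named
#' sub-streams (network, fluxes, noise, removal, decoys), so a dataset is a
#' pure function of its seed.
#'
#' @param m,n_I,m_E network dimensions (metabolites, internal reactions,
#'   measured exchange fluxes).
#' @param cov noise coefficient of variation (fraction).
#' @param n_O number of reactions to omit from the working model (0 for a
#'   correctly specified scenario).
#' @param decoys also draw a decoy candidate block of size `n_O`.
#' @param seed master integer seed.
#' @param homoscedastic fixed-sd noise variant.
#' @return A list with the model, blocks, `v_I`, the simulation output of
#'   [simulate_measurements()], a measurement data frame (`reaction_id`,
#'   `value`, `sd`) for the exchange fluxes, and (when `n_O > 0`) `X`
#'   (reduced design), `S_O`, `v_O`, `omitted_ids`, and `Z_decoy`.
#' @export
simulate_mfa_dataset <- function(m, n_I, m_E, cov, n_O = 0, decoys = FALSE,
                                 seed = 1L, homoscedastic = FALSE) {
  model <- random_stoichiometry(m, n_I, m_E, seed = derive_seed(seed, "network"))
  blocks <- attach_exchanges(model, m_E)
  v_I <- sample_internal_fluxes(blocks$S_I_NE, seed = derive_seed(seed, "fluxes"))
  sim <- simulate_measurements(v_I, blocks, cov, seed = derive_seed(seed, "noise"),
                               homoscedastic = homoscedastic)
  sd_meas <- if (homoscedastic) sim$sd else cov * abs(sim$v_E_obs)
  measurements <- data.frame(reaction_id = blocks$exchange_ids,
                             value = as.numeric(sim$v_E_obs),
                             sd = as.numeric(sd_meas),
                             stringsAsFactors = FALSE)
  out <- list(model = model, blocks = blocks, v_I = v_I, sim = sim,
              measurements = measurements)
  if (n_O > 0) {
    mis <- make_misspecified(model, n_O, seed = derive_seed(seed, "removal"))
    out$X <- mis$reduced
    out$S_O <- mis$S_O
    out$v_O <- v_I[mis$omitted_ids]
    out$omitted_ids <- mis$omitted_ids
    if (decoys) {
      out$Z_decoy <- make_decoy_reactions(mis$reduced, n_O,
                                          seed = derive_seed(seed, "decoys"))
    }
  }
  out
}
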