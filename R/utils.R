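# Shared numerical helpers (internal).

# Singular-value rank with the usual LAPACK-style default threshold:
# max(dim) * eps * largest singular value.
svd_rank <- function(M, tol = NULL) {
  sv <- svd(M, nu = 0, nv = 0)$d
  if (is.null(tol)) {
    tol <- max(dim(M)) * .Machine$double.eps * max(sv, 0)
  }
  list(rank = sum(sv > tol), singular_values = sv, tolerance = tol)
}

# Lower-triangular whitening solve: given cov = t(U) %*% U from chol(),
# returns solve(L, A) with L = t(U), so that whitened quantities have
# identity error covariance.
whiten_with <- function(chol_upper, A) {
  forwardsolve(t(chol_upper), A)
}

# Deterministic sub-seed derivation so that independent random streams
# (network, fluxes, noise, removal, decoys) can be driven from one master
# seed.  Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(as.character(stream))
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 10007 + 12345) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.  seed = NULL uses the current
# stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
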