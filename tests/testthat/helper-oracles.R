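# Independent oracles used across test files.  These deliberately avoid the
# package's QR/SVD code paths.

# Exact rank of an integer matrix by fraction-free (Bareiss) elimination.
# All intermediate values are minors of the input, so arithmetic stays exact
# in doubles for the small matrices used in tests; integrality is asserted
# at every step.
exact_rank <- function(A) {
  A <- as.matrix(A) * 1.0
  stopifnot(all(A == round(A)))
  m <- nrow(A)
  n <- ncol(A)
  r <- 0L
  prev <- 1
  for (col in seq_len(n)) {
    if (r == m) break
    rows <- (r + 1L):m
    nz <- rows[A[rows, col] != 0]
    if (!length(nz)) next
    piv <- nz[1]
    if (piv != r + 1L) A[c(r + 1L, piv), ] <- A[c(piv, r + 1L), ]
    p <- A[r + 1L, col]
    if (r + 1L < m) {
      for (i in (r + 2L):m) {
        A[i, ] <- (A[i, ] * p - A[r + 1L, ] * A[i, col]) / prev
        stopifnot(all(A[i, ] == round(A[i, ])))
      }
    }
    prev <- p
    r <- r + 1L
  }
  r
}

# Exact determinant of a small integer matrix by cofactor expansion.
int_det <- function(M) {
  n <- nrow(M)
  if (n == 1L) return(M[1, 1])
  s <- 0
  for (j in seq_len(n)) {
    if (M[1, j] != 0) {
      s <- s + (-1)^(j + 1) * M[1, j] * int_det(M[-1, -j, drop = FALSE])
    }
  }
  s
}

# Exact rational solution of the normal equations X'X b = X'y for integer
# X, y via Cramer's rule (numerators/denominator are exact integer
# determinants).
cramer_normal_equations <- function(X, y) {
  stopifnot(all(X == round(X)), all(y == round(y)))
  A <- crossprod(X)
  b <- as.numeric(crossprod(X, y))
  d <- int_det(A)
  stopifnot(d != 0)
  vapply(seq_len(ncol(A)), function(j) {
    Aj <- A
    Aj[, j] <- b
    int_det(Aj) / d
  }, numeric(1))
}

# Random integer matrix with entries in [-2, 2] (no all-zero rows).
random_int_matrix <- function(m, n) {
  repeat {
    M <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
    if (all(rowSums(M != 0) > 0)) return(M)
  }
}
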