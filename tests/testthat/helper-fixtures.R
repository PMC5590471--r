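# Small fixtures built in code.

# 4-metabolite, 4-reaction toy with two exchange reactions:
#   EX_A supplies A, EX_B supplies B, R1: A -> B + C, R2: B -> D.
toy_model <- function() {
  S <- cbind(EX_A = c(1, 0, 0, 0),
             EX_B = c(0, 1, 0, 0),
             R1 = c(-1, 1, 1, 0),
             R2 = c(0, -1, 0, 1))
  rownames(S) <- c("A", "B", "C", "D")
  flux_model(S)
}

toy_measurements <- function() {
  data.frame(reaction_id = c("EX_A", "EX_B"), value = c(2, 1),
             sd = c(0.1, 0.2), stringsAsFactors = FALSE)
}

# A well-conditioned random regression problem wrapped in the package type.
make_problem <- function(y, X, cov_e = NULL) {
  regression_problem(y, X, cov_e)
}

# Small in-silico scenario used by several tests (fast to generate).
small_scenario <- function(seed = 1, cov = 0.01, n_O = 2) {
  simulate_mfa_dataset(m = 30, n_I = 18, m_E = 15, cov = cov,
                       n_O = n_O, decoys = n_O > 0, seed = seed)
}

write_tsv_model <- function(model) {
  path <- tempfile("model-", fileext = ".tsv")
  write_flux_model(model, path)
  path
}
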