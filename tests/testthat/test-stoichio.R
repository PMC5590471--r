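test_that("model round-trips through the TSV format exactly", {
  model <- toy_model()
  path <- write_tsv_model(model)
  back <- read_flux_model(path)
  expect_identical(back$S, model$S)
  expect_identical(back$metabolite_ids, model$metabolite_ids)
  # a second round trip is bit-stable
  path2 <- file.path(dirname(path), "model2.tsv")
  write_flux_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("model validation rejects malformed tables", {
  dir <- withr::local_tempdir()
  # all-zero metabolite row
  bad <- file.path(dir, "orphan.tsv")
  writeLines(c("metabolite\tR1\tR2", "A\t1\t0", "B\t-1\t1", "C\t0\t0"), bad)
  expect_error(read_flux_model(bad), "orphan species C")
  # non-numeric body
  bad2 <- file.path(dir, "nonnum.tsv")
  writeLines(c("metabolite\tR1", "A\t1", "B\tx"), bad2)
  expect_error(read_flux_model(bad2), "non-numeric")
  # duplicate metabolite ids
  bad3 <- file.path(dir, "dup.tsv")
  writeLines(c("metabolite\tR1\tR2", "A\t1\t-1", "A\t-1\t1"), bad3)
  expect_error(read_flux_model(bad3), "duplicate metabolite")
})

test_that("partitioning splits exchange and internal blocks as a column permutation", {
  model <- toy_model()
  meas <- toy_measurements()
  pm <- partition_model(model, meas)
  # hand-written block matrices for the 4x4 toy
  expect_identical(pm$S_E, model$S[, c("EX_A", "EX_B")])
  expect_identical(pm$S_I, model$S[, c("R1", "R2")])
  expect_equal(unname(pm$v_E), c(2, 1))
  expect_identical(cbind(pm$S_E, pm$S_I)[, model$reaction_ids], model$S)
  # measurement order drives the S_E column order
  pm2 <- partition_model(model, meas[2:1, ])
  expect_identical(colnames(pm2$S_E), c("EX_B", "EX_A"))
})

test_that("partitioning rejects degenerate measurement sets", {
  model <- toy_model()
  all_meas <- data.frame(reaction_id = model$reaction_ids,
                         value = 1, sd = 0.1)
  expect_error(partition_model(model, all_meas), "nothing to estimate")
  expect_error(partition_model(model, data.frame(reaction_id = "nope",
                                                 value = 1, sd = 0)),
               "not in model")
  # rank-deficient internal block: duplicated internal reaction
  S <- cbind(EX_A = c(1, 0), R1 = c(-1, 1), R1b = c(-1, 1))
  rownames(S) <- c("A", "B")
  expect_error(partition_model(flux_model(S), data.frame(reaction_id = "EX_A",
                                                         value = 1, sd = 0.1)),
               "rank deficient")
})

test_that("numerical rank agrees with exact rational elimination on integer matrices", {
  expect_true(check_estimability(diag(3))$is_estimable)
  dup <- cbind(diag(3), c(1, 0, 0))
  expect_identical(check_estimability(dup)$numerical_rank, 3L)
  expect_false(check_estimability(dup)$is_estimable)
  set.seed(41)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    n <- sample(2:m, 1)
    M <- random_int_matrix(m, n)
    # sometimes force a dependent column
    if (i %% 3 == 0 && n >= 3) M[, n] <- M[, 1] - 2 * M[, 2]
    expect_identical(check_estimability(M)$numerical_rank, as.integer(exact_rank(M)),
                     label = sprintf("case %d (%dx%d)", i, m, n))
  }
})

test_that("reaction removal preserves retained columns and guards orphans", {
  model <- toy_model()
  expect_identical(remove_reactions(model, character()), model)
  # D only participates in R2
  expect_error(remove_reactions(model, "R2"), "orphan species D")
  red <- remove_reactions(model, "R2", forbid_orphans = FALSE)
  expect_identical(red$S[, c("EX_A", "EX_B", "R1")],
                   model$S[, c("EX_A", "EX_B", "R1")])
  # 3x4 toy where each species is touched by two reactions: removal legal
  S <- cbind(R1 = c(1, -1, 0), R2 = c(-1, 0, 1), R3 = c(0, 1, -1),
             R4 = c(1, -1, 1))
  rownames(S) <- c("X", "Y", "Z")
  red2 <- remove_reactions(flux_model(S), c("R4"))
  expect_true(all(rowSums(red2$S != 0) >= 1))
  expect_identical(colnames(red2$S), c("R1", "R2", "R3"))
})

test_that("candidate blocks align to the model's metabolite order", {
  model <- toy_model()
  dir <- withr::local_tempdir()
  cand <- file.path(dir, "cand.tsv")
  writeLines(c("metabolite\tC1", "B\t1", "A\t-1", "C\t0", "D\t0"), cand)
  Z <- read_reaction_block(cand, model)
  expect_identical(rownames(Z), model$metabolite_ids)
  expect_equal(unname(Z[, "C1"]), c(-1, 1, 0, 0))
  # strict row matching by default
  cand2 <- file.path(dir, "cand2.tsv")
  writeLines(c("metabolite\tC1", "A\t-1", "B\t1"), cand2)
  expect_error(read_reaction_block(cand2, model), "missing metabolite")
  Z2 <- read_reaction_block(cand2, model, allow_missing_rows = TRUE)
  expect_equal(unname(Z2[, "C1"]), c(-1, 1, 0, 0))
})
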