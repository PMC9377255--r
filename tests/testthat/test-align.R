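params <- alignment_params()

test_that("identical sequences align gap-free at identity 1", {
  a <- align_pair("ACDEFGHIKL", "ACDEFGHIKL", params)
  expect_equal(a$identity, 1)
  expect_equal(a$n_aligned, 10)
  expect_false(grepl("-", a$aligned_query))
})

test_that("single substitution gives 9/10 identical columns", {
  a <- align_pair("ACDEFGHIKL", "ACDEFGHIKV", params)
  expect_equal(a$n_aligned, 10)
  expect_equal(a$n_identical, 9)
  expect_equal(a$identity, 0.9)
})

test_that("positive-scoreless pair yields an empty alignment with identity 0", {
  # BLOSUM62 scores A/C substitutions at 0: no positive cell exists
  a <- align_pair("AAAA", "CCCC", params)
  expect_equal(a$score, 0)
  expect_equal(a$identity, 0)
  expect_equal(a$n_aligned, 0)
})

test_that("empty sequences are rejected", {
  expect_error(align_pair("", "ACD", params), "empty")
})

test_that("de-gapping the aligned rows recovers subsequences of the inputs", {
  set.seed(42)
  for (i in 1:10) {
    q <- random_aa(80)
    t <- random_aa(90)
    a <- align_pair(q, t, params)
    if (a$n_aligned == 0) next
    expect_true(grepl(gsub("-", "", a$aligned_query), q, fixed = TRUE))
    expect_true(grepl(gsub("-", "", a$aligned_target), t, fixed = TRUE))
    expect_equal(nchar(a$aligned_query), nchar(a$aligned_target))
  }
})

test_that("aligner agrees exactly with a plain-R full-DP oracle", {
  set.seed(7)
  submat <- params$submat
  rownames(submat) <- colnames(submat) <- c(AA20, "X")
  for (i in 1:25) {
    # mix of related (mutated copies) and unrelated pairs
    q <- random_aa(sample(20:60, 1))
    t <- if (i %% 2 == 0) {
      ch <- strsplit(q, "")[[1]]
      k <- ceiling(length(ch) * 0.3)
      idx <- sample(length(ch), k)
      ch[idx] <- sample(AA20, k, replace = TRUE)
      paste(ch, collapse = "")
    } else random_aa(sample(20:60, 1))
    a <- align_pair(q, t, params)
    o <- sw_oracle(q, t, submat, params$gap_open, params$gap_ext)
    expect_equal(a$score, o$score)
    expect_equal(a$n_identical, o$n_identical)
    expect_equal(a$n_aligned, o$n_aligned)
    # the vectorized oracle reproduces the quadratic one column for column
    of <- sw_oracle_fast(q, t, submat, params$gap_open, params$gap_ext)
    expect_equal(of$score, o$score)
    expect_equal(of$q_idx, a$q_idx)
    expect_equal(of$t_idx, a$t_idx)
  }
})

test_that("alignment scores match Biostrings pairwiseAlignment", {
  set.seed(11)
  for (i in 1:8) {
    q <- random_aa(150)
    ch <- strsplit(q, "")[[1]]
    idx <- sample(150, 60)
    ch[idx] <- sample(AA20, 60, replace = TRUE)
    t <- paste(c(ch, strsplit(random_aa(40), "")[[1]]), collapse = "")
    a <- align_pair(q, t, params)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(t),
      substitutionMatrix = "BLOSUM62", gapOpening = params$gap_open,
      gapExtension = params$gap_ext, type = "local")
    expect_equal(a$score, Biostrings::score(pa))
  }
})

test_that("column map is consistent with the aligned strings", {
  q <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  t <- "MKTAYIAKQRQISFVKWWSHFSRQLEERLGLIEVQ"  # insertion in target
  a <- align_pair(q, t, params)
  for (tp in which(!is.na(a$column_map))) {
    qp <- a$column_map[tp]
    k <- which(a$t_idx == tp)
    expect_equal(a$q_idx[k], qp)
  }
})

test_that("screening identity applies the coverage floor", {
  reps <- default_reps()
  set.seed(3)
  # unrelated random sequence: short spurious alignment, sub-floor coverage
  a <- align_pair(random_aa(400), reps[[1]]$seq, params)
  expect_lt(a$coverage, params$min_coverage)
  expect_equal(gusome:::screening_identity(a, params), 0)
  # a real homolog keeps near-full coverage and its raw identity
  s <- mutate_to_identity(reps[[1]]$seq, 0.6, reps[[1]]$cat_pos, seed = 2,
                          params = params)
  a2 <- align_pair(as.character(s), reps[[1]]$seq, params)
  expect_gt(a2$coverage, 0.9)
  expect_equal(gusome:::screening_identity(a2, params), a2$identity)
})
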