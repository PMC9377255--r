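params <- alignment_params()

test_that("a representative screens against itself as a perfect GUS call", {
  reps <- default_reps()
  r <- reps[[1]]
  call <- screen_candidate(list(id = "self", seq = r$seq), reps,
                           params = params)
  expect_true(call$accepted)
  expect_equal(call$best_identity, 1)
  expect_true(all(call$residue_matches))
  expect_equal(call$best_rep, r$id)
  expect_equal(call$reject_reason, "none")
})

test_that("ablating one catalytic residue rejects with missing_residue at 6/7", {
  reps <- default_reps()
  r <- reps[[2]]
  ch <- strsplit(r$seq, "")[[1]]
  ch[r$cat_pos[4]] <- "A"
  call <- screen_candidate(list(id = "abl", seq = paste(ch, collapse = "")),
                           reps, params = params)
  expect_false(call$accepted)
  expect_equal(call$reject_reason, "missing_residue")
  expect_equal(sum(call$residue_matches), 6)
})

test_that("conservative substitution at a catalytic position does not count", {
  reps <- default_reps()
  r <- reps[[1]]
  glu <- which(r$cat_res == "E")[1]
  ch <- strsplit(r$seq, "")[[1]]
  ch[r$cat_pos[glu]] <- "D"  # E -> D, chemically similar but not identical
  aln <- align_pair(paste(ch, collapse = ""), r$seq, params)
  res <- check_conserved_residues(aln, r)
  expect_false(res[glu])
  expect_equal(sum(res), 6)
})

test_that("a gap spanning a catalytic position marks it unconserved", {
  reps <- default_reps()
  r <- reps[[1]]
  p <- r$cat_pos[3]
  # delete a window around the catalytic position
  q <- paste0(substr(r$seq, 1, p - 6), substr(r$seq, p + 6, nchar(r$seq)))
  aln <- align_pair(q, r$seq, params)
  res <- check_conserved_residues(aln, r)
  expect_false(res[3])
})

test_that("annotation outside the target sequence errors", {
  reps <- default_reps()
  r <- reps[[1]]
  fake <- r
  fake$cat_pos[1] <- nchar(r$seq) + 10
  aln <- align_pair(r$seq, r$seq, params)
  expect_error(check_conserved_residues(aln, fake), "outside")
})

test_that("the identity threshold is strict and monotone in the accepted set", {
  reps <- default_reps()[1:4]
  set.seed(9)
  cands <- data.frame(
    id = paste0("c", 1:6),
    seq = vapply(1:6, function(i) {
      r <- reps[[(i - 1) %% 4 + 1]]
      as.character(mutate_to_identity(r$seq, runif(1, 0.3, 0.8), r$cat_pos,
                                      seed = 100 + i, params = params))
    }, ""),
    stringsAsFactors = FALSE)
  accepted <- lapply(c(0.25, 0.40, 0.60), function(th) {
    calls <- screen_catalog(cands, reps, threshold = th, params = params)
    calls$candidate_id[calls$accepted]
  })
  expect_true(all(accepted[[2]] %in% accepted[[1]]))
  expect_true(all(accepted[[3]] %in% accepted[[2]]))
  # strictness: a candidate exactly at the threshold is rejected
  calls <- screen_catalog(cands[1, , drop = FALSE], reps,
                          threshold = 1.0, params = params)
  expect_false(calls$accepted)  # identity <= 1 never beats strict > 1
})

test_that("greedy clustering merges identical sequences and splits at 0.85", {
  set.seed(21)
  s <- random_aa(200)
  two_same <- data.frame(id = c("b", "a"), seq = c(s, s),
                         stringsAsFactors = FALSE)
  cl <- cluster_greedy(two_same, 0.90, params)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$representative, "a")  # equal length: id ascending

  s85 <- as.character(mutate_to_identity(s, 0.85, seed = 5, params = params))
  pair <- data.frame(id = c("x", "y"), seq = c(s, s85),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_greedy(pair, 0.90, params)), 2)
  expect_equal(nrow(cluster_greedy(pair, 0.80, params)), 1)
})

test_that("clustering recovers planted groups and satisfies its postcondition", {
  reps <- default_reps()
  set.seed(31)
  scaffolds <- vapply(reps[c(1, 5, 10, 16)], `[[`, "", "seq")
  members <- list()
  for (g in seq_along(scaffolds)) {
    for (m in 1:3) {
      members[[length(members) + 1]] <- data.frame(
        id = sprintf("g%d_m%d", g, m),
        seq = as.character(mutate_to_identity(scaffolds[g],
                                              runif(1, 0.965, 0.99),
                                              seed = g * 10 + m,
                                              params = params)),
        stringsAsFactors = FALSE)
    }
  }
  acc <- do.call(rbind, members)
  cl <- cluster_greedy(acc, 0.90, params)
  expect_equal(nrow(cl), 4)
  # postcondition: every member >= threshold identity to its representative
  for (k in seq_len(nrow(cl))) {
    rep_seq <- acc$seq[acc$id == cl$representative[k]]
    for (mid in strsplit(cl$members[k], ",")[[1]]) {
      expect_gte(pairwise_identity(acc$seq[acc$id == mid], rep_seq, params),
                 0.90)
    }
  }
  # order invariance after the length sort: permuted input, same partition
  perm <- acc[sample(nrow(acc)), ]
  cl2 <- cluster_greedy(perm, 0.90, params)
  expect_equal(cl$members, cl2$members)
  # monotonicity: higher threshold never decreases cluster count
  expect_gte(nrow(cluster_greedy(acc, 0.97, params)), nrow(cl))
})

test_that("class assignment returns each representative's own class", {
  reps <- default_reps()
  for (r in reps[c(1, 5, 8, 11, 12, 16)]) {
    expect_equal(assign_class(r$seq, reps, params = params)$gus_class,
                 r$gus_class, info = r$id)
  }
})

test_that("a long insertion in the loop-1 window upgrades No Loop to Loop 1", {
  reps <- default_reps()
  nl <- Filter(function(r) r$gus_class == "NL", reps)[[1]]
  w <- nl$loop1
  set.seed(8)
  ins <- random_aa(17)
  q <- paste0(substr(nl$seq, 1, w[1]), ins,
              substr(nl$seq, w[1] + 1, nchar(nl$seq)))
  res <- assign_class(q, reps, params = params)
  expect_equal(res$gus_class, "L1")
  expect_gte(res$loop1_len, 12)
})

test_that("taxonomy assignment picks the nearest label and respects the floor", {
  reps <- default_reps()
  r <- reps[[3]]
  tx <- assign_taxonomy(r$seq, reps, params = params)
  expect_equal(tx$taxonomy, r$taxonomy)
  expect_equal(tx$identity, 1)

  s <- as.character(mutate_to_identity(r$seq, 0.8, seed = 4, params = params))
  expect_equal(assign_taxonomy(s, reps, params = params)$taxonomy, r$taxonomy)
  expect_equal(assign_taxonomy(s, reps, floor = 0.95,
                               params = params)$taxonomy, "unassigned")
})
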