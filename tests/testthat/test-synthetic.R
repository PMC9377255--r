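params <- alignment_params()

test_that("mutate_to_identity hits its target band and honours preservation", {
  reps <- default_reps()
  r <- reps[[1]]
  expect_identical(as.character(mutate_to_identity(r$seq, 1.0, seed = 1,
                                                   params = params)),
                   r$seq)
  s <- mutate_to_identity(r$seq, 0.90, r$cat_pos, seed = 3, params = params)
  id <- pairwise_identity(as.character(s), r$seq, params)
  expect_gte(id, 0.88)
  expect_lte(id, 0.92)
  ch <- strsplit(as.character(s), "")[[1]]
  expect_equal(ch[r$cat_pos], r$cat_res)
})

test_that("targets below the preserved-position floor error with the floor", {
  scaffold <- random_aa(100)
  expect_error(mutate_to_identity(scaffold, 0.01, preserve = 1:7, seed = 1,
                                  params = params),
               "floor 0.070")
})

test_that("indel mode still lands inside the identity band", {
  reps <- default_reps()
  r <- reps[[2]]
  s <- mutate_to_identity(r$seq, 0.7, r$cat_pos, seed = 6, params = params,
                          indels = TRUE)
  expect_true(abs(attr(s, "measured_identity") - 0.7) <= 0.02)
})

test_that("decoy-only catalogs yield zero accepted GUS calls", {
  reps <- default_reps()
  cc <- quiet(generate_catalog(c(FMN = 0),
                               c(residue_ablated = 2, low_identity = 2,
                                 random = 2),
                               reps, seed = 17, params = params))
  expect_true(all(!cc$truth$is_gus))
  calls <- screen_catalog(cc$catalog, reps, params = params)
  expect_equal(sum(calls$accepted), 0)
})

test_that("exactly the true GUS entries carry all seven residues", {
  reps <- default_reps()
  cc <- quiet(generate_catalog(c(FMN = 5, L1 = 5),
                               c(residue_ablated = 10),
                               reps, seed = 29, params = params))
  # residue-check oracle: align each entry to its source representative
  n_full <- 0
  for (i in seq_len(nrow(cc$catalog))) {
    src <- cc$truth$source_rep[i]
    rep <- reps[[src]]
    aln <- align_pair(cc$catalog$seq[i], rep$seq, params)
    if (all(check_conserved_residues(aln, rep))) n_full <- n_full + 1
  }
  expect_equal(n_full, 10)
})

test_that("generators are pure functions of the seed", {
  reps <- default_reps()
  a <- quiet(generate_catalog(c(FMN = 2, NL = 2), c(random = 2), reps,
                              seed = 5, params = params))
  b <- quiet(generate_catalog(c(FMN = 2, NL = 2), c(random = 2), reps,
                              seed = 5, params = params))
  expect_identical(a, b)
  cnt_a <- generate_counts(a$catalog, c("S1", "S2", "S3"), 0.002, seed = 9)
  cnt_b <- generate_counts(b$catalog, c("S1", "S2", "S3"), 0.002, seed = 9)
  expect_identical(cnt_a, cnt_b)
})

test_that("count generator plants a recoverable length bias", {
  set.seed(51)
  catalog <- data.frame(id = sprintf("g%03d", 1:80),
                        length = sample(150:700, 80, replace = TRUE),
                        stringsAsFactors = FALSE)
  samples <- paste0("S", 1:6)

  # Per-gene abundance noise is shared across a cohort's samples, so the
  # calibration fits are per sample, where residuals are independent.
  # null case: no planted bias
  cnt0 <- generate_counts(catalog, samples, bias_slope = 0, seed = 2)
  ab0 <- abundance_table(cnt0)
  f0 <- fit_length_bias(ab0$relative[, 1], ab0$lengths)
  expect_lt(abs(f0$slope), 2 * f0$slope_se)

  # library sizes span at least two-fold
  totals <- colSums(as.matrix(cnt0[, samples]))
  expect_gte(max(totals) / min(totals), 2)

  # planted slope falls inside its 95% CI in >= 90% of 50 replicates
  s_true <- 0.0015
  hits <- 0
  for (k in 1:50) {
    cnt <- generate_counts(catalog, samples, bias_slope = s_true, seed = k)
    ab <- abundance_table(cnt)
    f <- fit_length_bias(ab$relative[, 1], ab$lengths)
    ci <- f$slope + c(-1.96, 1.96) * f$slope_se
    if (s_true >= ci[1] && s_true <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  # enumerated: MK | AAAR | FFFK with all fragments shorter than 7 dropped
  expect_equal(digest_tryptic("MKAAARFFFK"), character(0))
  expect_equal(digest_tryptic("MKAAARFFFK", min_len = 2),
               c("MK", "AAAR", "FFFK"))
  # K before P does not cleave
  expect_equal(digest_tryptic("AAAKPAAAK", min_len = 2), c("AAAKPAAAK"))
  set.seed(61)
  for (i in 1:20) {
    s <- random_aa(sample(30:120, 1))
    expect_equal(digest_tryptic(s), digest_oracle(s), info = s)
  }
})

test_that("proteome generator plants the class intensity shift", {
  reps <- default_reps()
  cc <- quiet(generate_catalog(c(FMN = 4, NL = 4), c(), reps, seed = 71,
                               params = params))
  meta <- default_metadata()
  diffs <- vapply(1:6, function(k) {
    pr <- generate_proteome(cc$catalog, cc$truth, meta,
                            class_effects = c(FMN = 2), seed = 200 + k,
                            expressed_fraction = 1)
    fmn <- pr$class_log2$FMN
    g <- meta$group[match(pr$class_log2$sample_id, meta$sample_id)]
    mean(fmn[g == "MMF_recipient"]) - mean(fmn[g == "healthy"])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 2), 0.5)
})

test_that("zero expressed proteins yield an empty peptide table", {
  reps <- default_reps()
  cc <- quiet(generate_catalog(c(FMN = 2), c(), reps, seed = 81,
                               params = params))
  pr <- generate_proteome(cc$catalog, cc$truth, default_metadata(),
                          expressed_fraction = 0, seed = 1)
  expect_equal(nrow(pr$peptides), 0)
})

test_that("time-course generator reproduces the planted linear decline", {
  # b = 0, no noise: every sample shares rate a exactly
  tc0 <- generate_timecourses(c(A = 1, B = 3), a = 7, b = 0, noise_sd = 0,
                              meas_sd = 0, seed = 1)
  expect_equal(unique(tc0$truth$true_rate_nM_s), 7)
  r <- fit_rates(tc0$timecourses)
  expect_equal(r$rate_nM_s, c(7, 7), tolerance = 1e-12)

  # a = 10, b = 5, fmn = 2, no noise: true rate 20, fitted exactly
  tc <- generate_timecourses(c(S = 2), a = 10, b = 5, noise_sd = 0,
                             meas_sd = 0, seed = 2)
  expect_equal(tc$truth$true_rate_nM_s, 20)
  expect_equal(fit_rates(tc$timecourses)$rate_nM_s, 20, tolerance = 1e-10)

  # default design: five endpoints including 0, three replicates
  expect_equal(nrow(tc$timecourses), 15)
  expect_equal(sort(unique(tc$timecourses$time_s)),
               c(0, 15, 30, 45, 60) * 60)

  expect_error(generate_timecourses(c(S = 1), start_nM = -5), "positive")
})

test_that("low-identity decoys stay below the screening floor by construction", {
  reps <- default_reps()
  cc <- quiet(generate_catalog(c(FMN = 0), c(low_identity = 3), reps,
                               seed = 91, params = params))
  for (i in seq_len(nrow(cc$catalog))) {
    ids <- vapply(reps, function(r) {
      gusome:::screening_identity(align_pair(cc$catalog$seq[i], r$seq,
                                             params), params)
    }, numeric(1))
    expect_lt(max(ids), 0.20)
  }
})
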