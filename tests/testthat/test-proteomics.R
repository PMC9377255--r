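make_db <- function() {
  # two clusters; c1 has two member proteins sharing a peptide
  catalog <- data.frame(
    id = c("p1", "p2", "p3"),
    seq = c("MMMMAAAAAAKVVVVVVVRGGGGGGG",
            "TTTTAAAAAAKWWWWWWWRCCCCCCC",
            "DDDDEEEEEEKFFFFFFFRHHHHHHH"),
    stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = c("GC001", "GC002"),
                         representative = c("p1", "p3"),
                         members = c("p1,p2", "p3"),
                         gus_class = c("FMN", "NL"),
                         stringsAsFactors = FALSE)
  list(catalog = catalog, clusters = clusters)
}

test_that("peptide mapping applies cluster-level uniqueness and I/L equivalence", {
  db <- make_db()
  peps <- data.frame(
    sample_id = "S1",
    peptide = c("AAAAAAK",    # in p1 and p2: same cluster -> unique
                "VVVVVVVR",   # only p1 -> unique
                "EEEEEEK",    # only p3 -> unique
                "ZZZZZZZZ",   # invalid characters -> error case below
                "QQQQQQQ"),   # matches nothing
    intensity = c(100, 50, 70, 1, 5),
    stringsAsFactors = FALSE)
  expect_error(map_peptides(peps, db$catalog, db$clusters), "invalid")
  peps <- peps[peps$peptide != "ZZZZZZZZ", ]
  m <- map_peptides(peps, db$catalog, db$clusters)
  expect_true(m$unique[m$peptide == "AAAAAAK"])
  expect_equal(m$matched_clusters[m$peptide == "AAAAAAK"], "GC001")
  expect_false(m$matched[m$peptide == "QQQQQQQ"])

  # I/L equivalence: an I-containing peptide matches the L-containing protein
  db2 <- make_db()
  db2$catalog$seq[1] <- sub("VVVVVVV", "LLLLLLL", db2$catalog$seq[1])
  p_il <- data.frame(sample_id = "S1", peptide = "IIIIIIIR", intensity = 10,
                     stringsAsFactors = FALSE)
  expect_true(map_peptides(p_il, db2$catalog, db2$clusters)$matched)
  expect_false(map_peptides(p_il, db2$catalog, db2$clusters,
                            il_equivalence = FALSE)$matched)
})

test_that("a peptide present in two clusters is excluded from quantification", {
  db <- make_db()
  db$catalog$seq[3] <- paste0(db$catalog$seq[3], "AAAAAAK")  # now shared
  peps <- data.frame(sample_id = "S1",
                     peptide = c("AAAAAAK", "VVVVVVVR"),
                     intensity = c(100, 50), stringsAsFactors = FALSE)
  m <- map_peptides(peps, db$catalog, db$clusters)
  expect_false(m$unique[m$peptide == "AAAAAAK"])
  expect_equal(m$n_clusters[m$peptide == "AAAAAAK"], 2)
  pi <- protein_intensity(m, db$clusters)
  expect_equal(pi$intensity[pi$cluster_id == "GC001"], 50)
  # removing the non-unique peptide changes no protein intensity
  pi2 <- protein_intensity(m[m$peptide != "AAAAAAK", ], db$clusters)
  expect_equal(pi, pi2)
})

test_that("protein intensity sums unique peptides then applies log2", {
  db <- make_db()
  peps <- data.frame(sample_id = c("S1", "S1", "S1"),
                     peptide = c("AAAAAAK", "VVVVVVVR", "VVVVVVVR"),
                     intensity = c(100, 50, 25), stringsAsFactors = FALSE)
  m <- map_peptides(peps, db$catalog, db$clusters)
  pi <- protein_intensity(m, db$clusters)
  expect_equal(pi$intensity, 175)  # duplicates summed
  expect_equal(pi$log2_intensity, log2(175))
  expect_equal(pi$gus_class, "FMN")
  # a protein with only unmatched/non-unique peptides yields no row
  expect_equal(nrow(pi[pi$cluster_id == "GC002", ]), 0)
  # arithmetic check from the summation rule
  m2 <- m; m2$intensity <- c(100, 50, 0)
  pi_arith <- protein_intensity(m2, db$clusters)
  expect_equal(pi_arith$log2_intensity, log2(150), tolerance = 1e-12)
  expect_equal(round(pi_arith$log2_intensity, 4), 7.2288)
})

test_that("sequence coverage equals the interval union", {
  prot <- random_aa(100)
  expect_equal(sequence_coverage(prot, substr(prot, 11, 20)), 0.10)
  expect_equal(sequence_coverage(prot, c(substr(prot, 11, 20),
                                         substr(prot, 16, 25))), 0.15)
  expect_equal(sequence_coverage(prot, character(0)), 0)
  expect_error(sequence_coverage(prot, "WWWWWWWWWWWW"), "does not match")
})

test_that("coverage matches the per-residue bitmap oracle on random sets", {
  set.seed(301)
  for (i in 1:25) {
    prot <- random_aa(sample(60:150, 1))
    k <- sample(1:6, 1)
    peps <- vapply(seq_len(k), function(j) {
      st <- sample(nchar(prot) - 12, 1)
      substr(prot, st, st + sample(6:12, 1))
    }, "")
    expect_equal(sequence_coverage(prot, peps), coverage_oracle(prot, peps))
  }
})

test_that("class intensities sum raw then log, never mean of logs", {
  rows <- data.frame(cluster_id = c("GC001", "GC002"),
                     sample_id = "S1",
                     intensity = c(2^10, 2^10),
                     log2_intensity = c(10, 10),
                     gus_class = "FMN", stringsAsFactors = FALSE)
  ci <- class_protein_abundance(rows)
  expect_equal(ci$log2_intensity, 11)
  expect_gte(ci$log2_intensity, max(rows$log2_intensity))
  ci2 <- class_protein_abundance(rows[2:1, ])
  expect_equal(ci, ci2)
})
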