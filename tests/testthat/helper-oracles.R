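# Independent oracles used across tests. These deliberately re-derive
# results from first principles (plain-R dynamic programming, per-residue
# bitmaps, full enumeration) rather than calling package internals.

# Full Smith-Waterman affine-gap DP in plain R with the same deterministic
# tie rules (best cell with smallest (row, col); diagonal > up > left).
# Returns score, n_identical, n_aligned of the optimal local alignment.
sw_oracle <- function(q, t, submat, open, ext) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[qc[i - 1], tc[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  best <- max(H)
  if (best == 0) return(list(score = 0, n_identical = 0, n_aligned = 0))
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- hit[1, 1]; j <- hit[1, 2]
  nid <- 0L; nal <- 0L
  state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      d <- H[i - 1, j - 1] + submat[qc[i - 1], tc[j - 1]]
      if (H[i, j] == d) {
        nal <- nal + 1L
        if (qc[i - 1] == tc[j - 1]) nid <- nid + 1L
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == F[i, j]) state <- "F"
      else state <- "E"
    } else if (state == "F") {
      if (F[i, j] == H[i - 1, j] - open - ext) state <- "H"
      i <- i - 1
    } else {
      if (E[i, j] == H[i, j - 1] - open - ext) state <- "H"
      j <- j - 1
    }
  }
  list(score = best, n_identical = nid, n_aligned = nal)
}

# Row-vectorized variant of the same DP (Gotoh forward sweep with a
# cumulative-max trick for the horizontal gap state), fast enough for
# full-length screening oracles. Stores all three state matrices and
# replays the traceback under the specified tie rules, returning the
# aligned column indices (0 = gap).
sw_oracle_fast <- function(q, t, submat, open, ext) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    srow <- submat[qc[i], tc]
    f <- pmax(H[i, jj + 1] - open - ext, F[i, jj + 1] - ext)
    d <- H[i, jj] + srow
    base <- pmax(0, pmax(d, f))
    # E[j] = max_{k<j}(H[k] - open - (j-k) ext); opening from an E cell is
    # never better than extending, so the chain can run over `base`
    A <- base + jj * ext
    cmA <- cummax(A)
    e <- c(-Inf, cmA[-m]) - open - jj * ext
    F[i + 1, jj + 1] <- f
    E[i + 1, jj + 1] <- e
    H[i + 1, jj + 1] <- pmax(base, e)
  }
  best <- max(H)
  if (best == 0) {
    return(list(score = 0, q_idx = integer(0), t_idx = integer(0)))
  }
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- as.integer(hit[1, 1]); j <- as.integer(hit[1, 2])
  qa <- integer(0); ta <- integer(0)
  state <- "H"
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      d <- H[i - 1, j - 1] + submat[qc[i - 1], tc[j - 1]]
      if (H[i, j] == d) {
        qa <- c(i - 1L, qa); ta <- c(j - 1L, ta)
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == F[i, j]) state <- "F"
      else state <- "E"
    } else if (state == "F") {
      qa <- c(i - 1L, qa); ta <- c(0L, ta)
      if (F[i, j] == H[i - 1, j] - open - ext) state <- "H"
      i <- i - 1
    } else {
      qa <- c(0L, qa); ta <- c(j - 1L, ta)
      if (E[i, j] == H[i, j - 1] - open - ext) state <- "H"
      j <- j - 1
    }
  }
  list(score = best, q_idx = as.integer(qa), t_idx = as.integer(ta))
}

# Per-residue bitmap coverage oracle.
coverage_oracle <- function(protein_seq, peptides) {
  s <- chartr("I", "L", protein_seq)
  hit <- rep(FALSE, nchar(s))
  for (p in chartr("I", "L", peptides)) {
    pos <- gregexpr(p, s, fixed = TRUE)[[1]]
    for (st in pos) if (st > 0) hit[st:(st + nchar(p) - 1)] <- TRUE
  }
  mean(hit)
}

# Exhaustive 2^n sign-pattern enumeration for the signed-rank test.
wilcoxon_oracle <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  wdist <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L)
    wdist[mask + 1] <- sum(r[signs == 1])
  }
  lo <- min(w_plus, w_minus); hi <- max(w_plus, w_minus)
  min(1, (sum(wdist <= lo) + sum(wdist >= hi)) / 2^n)
}

# Welch t-test from the textbook formulas.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Naive tryptic digestion oracle: scan every position, split after K/R not
# before P, then filter by length.
digest_oracle <- function(seq, min_len = 7, max_len = 30) {
  ch <- strsplit(seq, "")[[1]]
  peps <- character(); cur <- character()
  for (i in seq_along(ch)) {
    cur <- c(cur, ch[i])
    nxt <- if (i < length(ch)) ch[i + 1] else ""
    if (ch[i] %in% c("K", "R") && nxt != "P") {
      peps <- c(peps, paste(cur, collapse = "")); cur <- character()
    }
  }
  if (length(cur) > 0) peps <- c(peps, paste(cur, collapse = ""))
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Shared fixtures (computed once per test run).
default_reps <- local({
  reps <- NULL
  function() {
    if (is.null(reps)) reps <<- load_default_representatives()
    reps
  }
})

quiet <- function(expr) {
  old <- gus_verbose(FALSE)
  on.exit(gus_verbose(old))
  expr
}
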