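#' Alignment parameters
#'
#' Defaults mirror the protein-protein BLAST search conventions: BLOSUM62
#' scoring, gap existence 11, gap extension 1, local (Smith-Waterman)
#' alignment, identity computed over aligned (non-gap) columns.
#'
#' Because short spurious local alignments between unrelated proteins can
#' carry high column identity, a reported identity only counts as a hit for
#' screening when the alignment covers at least `min_coverage` of the
#' shorter sequence; below that floor the screening identity is 0 (no hit),
#' mirroring how a database search simply reports no alignment. Set
#' `min_coverage = 0` to disable.
#'
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM45"`).
#' @param gap_open,gap_ext non-negative gap penalties; a gap of length k
#'   costs `gap_open + k * gap_ext`.
#' @param identity_mode `"aligned"` (identical / aligned columns, default)
#'   or `"query"` (identical / query length).
#' @param min_coverage minimum fraction of the shorter sequence that must
#'   be aligned for the identity to count in screening.
#' @return a list of class `gus_align_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1,
                             identity_mode = c("aligned", "query"),
                             min_coverage = 0.30) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(gap_open >= 0, gap_ext >= 0, min_coverage >= 0, min_coverage <= 1)
  structure(list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext,
                 identity_mode = identity_mode, min_coverage = min_coverage,
                 submat = get_submatrix(matrix)),
            class = "gus_align_params")
}

# Substitution matrix restricted to the package alphabet, 0-based-code order.
get_submatrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  if (!all(AA_ALPHABET %in% rownames(m))) {
    stop("substitution matrix '", name, "' lacks required residues")
  }
  m[AA_ALPHABET, AA_ALPHABET]
}

encode_seq <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA_ALPHABET) - 1L
  if (anyNA(codes)) stop("invalid residue in sequence")
  codes
}

#' Optimal local pairwise alignment
#'
#' Smith-Waterman alignment under affine gap penalties with deterministic
#' tie-breaking: the traceback starts at the highest-scoring cell with the
#' smallest (query index, target index) pair, and prefers diagonal over up
#' (gap in target) over left (gap in query). An all-mismatch pair with no
#' positive-scoring cell yields an empty alignment with identity 0.
#'
#' @param query,target amino-acid strings (non-empty, package alphabet).
#' @param params a [alignment_params()] object.
#' @return an object of class `gus_alignment`: list with `score`,
#'   `aligned_query`, `aligned_target` (gap character `-`), `n_identical`,
#'   `n_aligned` (columns with residues in both rows), `identity`
#'   (`n_identical / n_aligned`, 0 for an empty alignment), `coverage`
#'   (aligned query residues / length of the shorter sequence),
#'   `column_map` (for each target residue index, the aligned query residue
#'   index or `NA`), and the 1-based `query_range` / `target_range`.
#' @export
align_pair <- function(query, target, params = alignment_params()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  res <- sw_align_cpp(encode_seq(query), encode_seq(target), params$submat,
                      params$gap_open, params$gap_ext)
  qi <- res$q_idx
  ti <- res$t_idx
  qchr <- strsplit(query, "", fixed = TRUE)[[1]]
  tchr <- strsplit(target, "", fixed = TRUE)[[1]]
  aq <- ifelse(qi > 0, qchr[pmax(qi, 1)], "-")
  at <- ifelse(ti > 0, tchr[pmax(ti, 1)], "-")
  both <- qi > 0 & ti > 0
  n_aligned <- sum(both)
  n_identical <- sum(both & aq == at)
  column_map <- rep(NA_integer_, length(tchr))
  if (length(ti) > 0) column_map[ti[both]] <- qi[both]
  structure(list(
    score = res$score,
    aligned_query = paste(aq, collapse = ""),
    aligned_target = paste(at, collapse = ""),
    n_identical = n_identical,
    n_aligned = n_aligned,
    identity = if (n_aligned > 0) n_identical / n_aligned else 0,
    coverage = sum(qi > 0) / min(length(qchr), length(tchr)),
    column_map = column_map,
    query_range = if (any(qi > 0)) range(qi[qi > 0]) else c(NA_integer_, NA_integer_),
    target_range = if (any(ti > 0)) range(ti[ti > 0]) else c(NA_integer_, NA_integer_),
    q_idx = qi, t_idx = ti,
    query_seq = query, target_seq = target,
    query_length = length(qchr), target_length = length(tchr)
  ), class = "gus_alignment")
}

#' @export
print.gus_alignment <- function(x, ...) {
  cat(sprintf("local alignment: score %.1f, identity %.3f (%d/%d), coverage %.2f\n",
              x$score, x$identity, x$n_identical, x$n_aligned, x$coverage))
  invisible(x)
}

# Identity used for a screening decision: honours identity_mode and the
# coverage floor (a sub-floor alignment is "no hit", identity 0).
screening_identity <- function(aln, params) {
  id <- switch(params$identity_mode,
               aligned = aln$identity,
               query = aln$n_identical / aln$query_length)
  if (aln$coverage < params$min_coverage) 0 else id
}

#' Pairwise identity between two sequences
#'
#' Convenience wrapper: aligns and returns the aligned-column identity.
#'
#' @inheritParams align_pair
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(query, target, params = alignment_params()) {
  align_pair(query, target, params)$identity
}
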