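#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, with no missed
#' cleavages; peptides of 7-30 residues are retained (typical detectable
#' range).
#'
#' @param seq amino-acid string.
#' @param min_len,max_len retained length range.
#' @return character vector of peptides, N- to C-terminal order.
#' @export
digest_tryptic <- function(seq, min_len = 7, max_len = 30) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1] != "P" |
                           cut_after == n]
  bounds <- c(0, cut_after, if (n %in% cut_after) NULL else n)
  bounds <- unique(bounds)
  peps <- substring(seq, head(bounds, -1) + 1, bounds[-1])
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

# I/L are isobaric and indistinguishable by standard MS searches.
il_normalize <- function(x) chartr("I", "L", x)

#' Map peptides to the clustered GUS catalog
#'
#' A peptide matches a protein iff it is an exact substring under I/L
#' equivalence (isoleucine and leucine are isobaric). Matches are recorded
#' at the cluster level; a peptide is `unique` iff it matches exactly one
#' cluster. Peptides matching no protein are flagged unmatched.
#'
#' @param peptides data.frame with `sample_id`, `peptide`, `intensity`.
#' @param catalog protein catalog data.frame (`id`, `seq`).
#' @param clusters cluster table (`cluster_id`, `members`); only member
#'   proteins constitute the search space.
#' @param il_equivalence treat I and L as identical (default `TRUE`).
#' @return the input with added columns `matched_clusters` (comma-sep ids,
#'   `""` if none), `n_clusters`, `unique`, `matched` (logical).
#' @export
map_peptides <- function(peptides, catalog, clusters, il_equivalence = TRUE) {
  stopifnot(all(c("sample_id", "peptide", "intensity") %in% names(peptides)))
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                peptides$peptide)
  if (any(bad)) {
    stop("invalid characters in peptide: ", peptides$peptide[which(bad)[1]])
  }
  member_ids <- strsplit(clusters$members, ",", fixed = TRUE)
  prot_ids <- unlist(member_ids)
  prot_cluster <- rep(clusters$cluster_id, lengths(member_ids))
  seqs <- catalog$seq[match(prot_ids, catalog$id)]
  if (anyNA(seqs)) stop("cluster member absent from catalog")
  norm <- if (il_equivalence) il_normalize else identity
  seqs_n <- norm(seqs)
  uniq_pep <- unique(peptides$peptide)
  hit <- lapply(norm(uniq_pep), function(p) {
    which(vapply(seqs_n, function(s) grepl(p, s, fixed = TRUE), logical(1)))
  })
  cl_of <- vapply(hit, function(ix)
    paste(sort(unique(prot_cluster[ix])), collapse = ","), "")
  ncl <- vapply(hit, function(ix) length(unique(prot_cluster[ix])), 0L)
  m <- match(peptides$peptide, uniq_pep)
  peptides$matched_clusters <- cl_of[m]
  peptides$n_clusters <- ncl[m]
  peptides$unique <- ncl[m] == 1L
  peptides$matched <- ncl[m] > 0L
  peptides
}

#' Protein (cluster) intensities from unique peptides
#'
#' Per (cluster, sample), the intensities of its unique peptides are
#' summed; rows are emitted only where the sum is positive (undetected
#' proteins are absent, not zero). log2 is applied after summation.
#'
#' @param matches output of [map_peptides()].
#' @param clusters cluster table (for `gus_class` annotation, optional).
#' @return data.frame with `cluster_id`, `sample_id`, `intensity`,
#'   `log2_intensity` and, when available, `gus_class`.
#' @export
protein_intensity <- function(matches, clusters = NULL) {
  u <- matches[matches$unique, , drop = FALSE]
  if (nrow(u) == 0) {
    out <- data.frame(cluster_id = character(), sample_id = character(),
                      intensity = numeric(), log2_intensity = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(intensity ~ matched_clusters + sample_id,
                            data = u, FUN = sum)
    names(agg)[1] <- "cluster_id"
    agg <- agg[agg$intensity > 0, , drop = FALSE]
    agg <- agg[order(agg$cluster_id, agg$sample_id), , drop = FALSE]
    agg$log2_intensity <- log2(agg$intensity)
    rownames(agg) <- NULL
    out <- agg
  }
  if (!is.null(clusters)) {
    out$gus_class <- clusters$gus_class[match(out$cluster_id,
                                              clusters$cluster_id)]
  }
  out
}

#' Fraction of a protein covered by matched peptides
#'
#' Union of the residue intervals of all occurrences of each matched
#' peptide (under I/L equivalence), divided by protein length.
#'
#' @param protein_seq amino-acid string.
#' @param peptides character vector of peptides; every peptide must occur
#'   in the protein.
#' @param il_equivalence treat I and L as identical.
#' @return coverage fraction in `[0, 1]`.
#' @export
sequence_coverage <- function(protein_seq, peptides, il_equivalence = TRUE) {
  n <- nchar(protein_seq)
  if (length(peptides) == 0) return(0)
  norm <- if (il_equivalence) il_normalize else identity
  s <- norm(protein_seq)
  intervals <- list()
  for (p in norm(unique(peptides))) {
    pos <- gregexpr(p, s, fixed = TRUE)[[1]]
    if (pos[1] == -1) stop("peptide does not match protein: ", p)
    for (st in pos) intervals[[length(intervals) + 1]] <- c(st, st + nchar(p) - 1)
  }
  iv <- do.call(rbind, intervals)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  covered <- 0
  cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur[2] + 1) {
      cur[2] <- max(cur[2], iv[i, 2])
    } else {
      covered <- covered + cur[2] - cur[1] + 1
      cur <- iv[i, ]
    }
  }
  covered <- covered + cur[2] - cur[1] + 1
  covered / n
}

#' Per-sample coverage of each detected cluster
#'
#' Coverage of the cluster representative by all peptides matched to the
#' cluster in that sample (unique or shared).
#'
#' @param matches output of [map_peptides()].
#' @param clusters cluster table.
#' @param catalog protein catalog.
#' @return data.frame `cluster_id`, `sample_id`, `coverage`.
#' @export
coverage_table <- function(matches, clusters, catalog) {
  hit <- matches[matches$matched, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(clusters))) {
    cid <- clusters$cluster_id[k]
    rep_seq <- catalog$seq[match(clusters$representative[k], catalog$id)]
    sel <- hit[grepl(cid, hit$matched_clusters, fixed = TRUE), , drop = FALSE]
    for (s in unique(sel$sample_id)) {
      peps <- sel$peptide[sel$sample_id == s]
      peps <- peps[vapply(il_normalize(peps), function(p)
        grepl(p, il_normalize(rep_seq), fixed = TRUE), logical(1))]
      if (length(peps) == 0) next
      out[[length(out) + 1]] <- data.frame(
        cluster_id = cid, sample_id = s,
        coverage = sequence_coverage(rep_seq, peps), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster_id = character(), sample_id = character(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Per-class summed protein intensity
#'
#' Raw intensities are summed within structural class per sample, then
#' log2-transformed (sum-then-log, never mean of logs). Classes undetected
#' in a sample are absent from the output.
#'
#' @param rows [protein_intensity()] output with `gus_class`.
#' @return data.frame `gus_class`, `sample_id`, `intensity`,
#'   `log2_intensity`.
#' @export
class_protein_abundance <- function(rows) {
  if (nrow(rows) == 0) {
    return(data.frame(gus_class = character(), sample_id = character(),
                      intensity = numeric(), log2_intensity = numeric(),
                      stringsAsFactors = FALSE))
  }
  stopifnot("gus_class" %in% names(rows))
  agg <- stats::aggregate(intensity ~ gus_class + sample_id, data = rows,
                          FUN = sum)
  agg <- agg[agg$intensity > 0, , drop = FALSE]
  agg <- agg[order(agg$gus_class, agg$sample_id), , drop = FALSE]
  agg$log2_intensity <- log2(agg$intensity)
  rownames(agg) <- NULL
  agg
}
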