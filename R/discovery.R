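#' Check conservation of the seven catalytic residues
#'
#' Given a candidate-vs-representative alignment, position i is conserved
#' iff the representative's i-th annotated catalytic position aligns to a
#' candidate residue (not a gap) identical to the annotated letter. The
#' match is exact: conservative substitutions (e.g. E to D) do not count.
#'
#' @param aln a [align_pair()] result whose target is the representative.
#' @param rep a representative record (see [read_representatives()]).
#' @return logical vector of length 7, ordered as the annotation.
#' @export
check_conserved_residues <- function(aln, rep) {
  if (any(rep$cat_pos > aln$target_length)) {
    stop("catalytic annotation outside representative sequence")
  }
  vapply(seq_along(rep$cat_pos), function(i) {
    qidx <- aln$column_map[rep$cat_pos[i]]
    if (is.na(qidx)) return(FALSE)
    substr(aln$query_seq, qidx, qidx) == rep$cat_res[i]
  }, logical(1))
}

align_to_rep <- function(seq, rep, params) align_pair(seq, rep$seq, params)

#' Screen one candidate protein against the representative GUS set
#'
#' The structure-guided screen: the candidate is aligned pairwise to every
#' representative; it is accepted as a GUS enzyme iff its best identity
#' strictly exceeds `threshold` (default the published 25% screen) and all
#' seven conserved catalytic residues are present in the alignment to the
#' best-identity representative (ties broken by input order). With
#' `residue_mode = "any"`, the heptad may instead be carried by any
#' representative above the identity threshold — useful when the best hit
#' is a representative of another subfamily whose alignment misregisters
#' the catalytic positions.
#'
#' @param candidate list or one-row data.frame with `id` and `seq`.
#' @param reps a `gus_representatives` set.
#' @param threshold identity threshold (strict `>`), default 0.25.
#' @param params [alignment_params()].
#' @param residue_mode `"best"` (default) or `"any"`.
#' @return a `gus_call` list: `candidate_id`, `best_rep`, `best_identity`,
#'   `residue_matches` (logical 7), `accepted`, `reject_reason` (one of
#'   `below_identity`, `missing_residue`, `none`).
#' @export
screen_candidate <- function(candidate, reps, threshold = 0.25,
                             params = alignment_params(),
                             residue_mode = c("best", "any")) {
  residue_mode <- match.arg(residue_mode)
  stopifnot(length(reps) > 0)
  alns <- lapply(reps, function(rep) align_to_rep(candidate$seq, rep, params))
  ids <- vapply(alns, screening_identity, numeric(1), params = params)
  best <- which.max(ids)  # ties -> first in input order
  best_id <- ids[[best]]
  res_best <- check_conserved_residues(alns[[best]], reps[[best]])
  if (best_id <= threshold) {
    accepted <- FALSE
    reason <- "below_identity"
    residue_matches <- res_best
  } else if (residue_mode == "best") {
    accepted <- all(res_best)
    reason <- if (accepted) "none" else "missing_residue"
    residue_matches <- res_best
  } else {
    ok <- which(ids > threshold)
    hits <- lapply(ok, function(k) check_conserved_residues(alns[[k]], reps[[k]]))
    full <- vapply(hits, all, logical(1))
    accepted <- any(full)
    reason <- if (accepted) "none" else "missing_residue"
    residue_matches <- if (accepted) hits[[which(full)[1]]] else res_best
  }
  structure(list(candidate_id = candidate$id,
                 best_rep = reps[[best]]$id,
                 best_identity = best_id,
                 residue_matches = residue_matches,
                 accepted = accepted,
                 reject_reason = reason),
            class = "gus_call")
}

#' Screen a whole catalog
#'
#' @param catalog data.frame from [read_protein_fasta()].
#' @inheritParams screen_candidate
#' @return data.frame with one row per candidate: `candidate_id`,
#'   `best_rep`, `best_identity`, `residues_matched` (0-7), `residues`
#'   (7-character string of `1`/`0` in annotation order), `accepted`,
#'   `reject_reason`.
#' @export
screen_catalog <- function(catalog, reps, threshold = 0.25,
                           params = alignment_params(),
                           residue_mode = "best") {
  calls <- lapply(seq_len(nrow(catalog)), function(i) {
    screen_candidate(catalog[i, ], reps, threshold, params, residue_mode)
  })
  data.frame(
    candidate_id = vapply(calls, `[[`, "", "candidate_id"),
    best_rep = vapply(calls, `[[`, "", "best_rep"),
    best_identity = vapply(calls, `[[`, 0, "best_identity"),
    residues_matched = vapply(calls, function(x) sum(x$residue_matches), 0L),
    residues = vapply(calls, function(x)
      paste(as.integer(x$residue_matches), collapse = ""), ""),
    accepted = vapply(calls, `[[`, TRUE, "accepted"),
    reject_reason = vapply(calls, `[[`, "", "reject_reason"),
    stringsAsFactors = FALSE
  )
}

#' Greedy redundancy clustering of accepted GUS sequences
#'
#' Greedy incremental scheme in the style of CD-HIT: sequences are sorted
#' by length descending (ties by id ascending); each joins the first
#' existing cluster whose representative it matches at `>= threshold`
#' aligned-column identity, otherwise it founds a new cluster. Cluster
#' representatives are therefore the longest member; output order is
#' founding order.
#'
#' @param accepted data.frame with `id`, `seq` (and `length`; recomputed if
#'   absent).
#' @param threshold identity threshold in (0, 1], default 0.90.
#' @param params [alignment_params()].
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `representative`, `n_members`, `members` (comma-separated ids).
#' @export
cluster_greedy <- function(accepted, threshold = 0.90,
                           params = alignment_params()) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(accepted) == 0) {
    return(data.frame(cluster_id = character(), representative = character(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  }
  len <- accepted$length %||% nchar(accepted$seq)
  ord <- order(-len, accepted$id)
  acc <- accepted[ord, , drop = FALSE]
  rep_idx <- integer(0)          # row index (in acc) of each cluster rep
  membership <- integer(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      id <- pairwise_identity(acc$seq[i], acc$seq[rep_idx[k]], params)
      if (id >= threshold) {
        membership[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      membership[i] <- length(rep_idx)
    }
  }
  data.frame(
    cluster_id = sprintf("GC%03d", seq_along(rep_idx)),
    representative = acc$id[rep_idx],
    n_members = as.integer(tabulate(membership, length(rep_idx))),
    members = vapply(seq_along(rep_idx), function(k)
      paste(acc$id[membership == k], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

#' Loop-length thresholds for structural class assignment
#'
#' Measured loop lengths at or above the `long` threshold give the full
#' loop classes (L1/L2); lengths in `[mini, long)` give the mini-loop
#' classes; both loops in the mini range or above give mL1_2; both below
#' the mini threshold give No Loop. `fmn_identity` is the identity cutoff
#' over the FMN representative's C-terminal segment for the FMN class.
#'
#' @param l1_long,l1_mini,l2_long,l2_mini residue-count thresholds.
#' @param fmn_identity fraction in (0, 1].
#' @return a named list.
#' @export
class_thresholds <- function(l1_long = 12, l1_mini = 5,
                             l2_long = 12, l2_mini = 5,
                             fmn_identity = 0.50) {
  list(l1_long = l1_long, l1_mini = l1_mini, l2_long = l2_long,
       l2_mini = l2_mini, fmn_identity = fmn_identity)
}

# Length of the query segment projected onto the target window [a, b]:
# the number of query residues strictly between the nearest aligned
# positions flanking the window (robust to gapping inside a divergent
# loop). Falls back to counting aligned residues across the window when a
# flank anchor is missing; NA when nothing near the window is aligned.
measure_loop <- function(aln, window) {
  cm <- aln$column_map
  lo <- which(!is.na(cm[seq_len(window[1] - 1)]))
  hi <- which(!is.na(cm)) ; hi <- hi[hi > window[2]]
  if (length(lo) > 0 && length(hi) > 0) {
    return(cm[min(hi)] - cm[max(lo)] - 1L)
  }
  cols <- which(aln$t_idx >= window[1] & aln$t_idx <= window[2] & aln$t_idx > 0)
  if (length(cols) == 0) return(NA_integer_)
  span <- seq(min(cols), max(cols))
  sum(aln$q_idx[span] > 0)
}

#' Assign a structural class to a cluster representative
#'
#' Two-step rule: (1) FMN test — if the identity over any FMN
#' representative's annotated C-terminal segment reaches
#' `thresholds$fmn_identity`, the class is FMN; (2) otherwise the sequence
#' is projected onto the highest-identity representative's loop windows via
#' the alignment column map, the laid-down segment lengths are measured,
#' and the class follows [class_thresholds()]. When neither loop window is
#' alignable the class of the highest-identity representative is used,
#' flagged `by_nearest`. Representatives tying on identity are resolved by
#' the fixed class order in [GUS_CLASSES] and flagged ambiguous.
#'
#' @param seq amino-acid string of the cluster representative.
#' @param reps `gus_representatives`.
#' @param thresholds [class_thresholds()].
#' @param params [alignment_params()].
#' @return list with `gus_class`, `method` (`fmn`, `loop_windows`,
#'   `by_nearest`), `ambiguous`, `nearest_rep`, `loop1_len`, `loop2_len`.
#' @export
assign_class <- function(seq, reps, thresholds = class_thresholds(),
                         params = alignment_params()) {
  alns <- lapply(reps, function(rep) align_to_rep(seq, rep, params))
  ids <- vapply(alns, `[[`, 0, "identity")
  if (all(ids == 0)) stop("no representative alignable")

  # FMN test over the annotated C-terminal segment
  for (k in seq_along(reps)) {
    fmn <- reps[[k]]$fmn
    if (is.null(fmn)) next
    aln <- alns[[k]]
    wlen <- fmn[2] - fmn[1] + 1
    qidx <- aln$column_map[fmn[1]:fmn[2]]
    tres <- strsplit(reps[[k]]$seq, "")[[1]][fmn[1]:fmn[2]]
    qres <- rep("-", wlen)
    qres[!is.na(qidx)] <- strsplit(seq, "")[[1]][qidx[!is.na(qidx)]]
    if (sum(qres == tres) / wlen >= thresholds$fmn_identity) {
      return(list(gus_class = "FMN", method = "fmn", ambiguous = FALSE,
                  nearest_rep = reps[[k]]$id,
                  loop1_len = NA_integer_, loop2_len = NA_integer_))
    }
  }

  best_id <- max(ids)
  tied <- which(ids == best_id)
  ambiguous <- FALSE
  if (length(tied) > 1) {
    classes <- vapply(tied, function(k) reps[[k]]$gus_class, "")
    if (length(unique(classes)) > 1) ambiguous <- TRUE
    tied <- tied[order(match(classes, GUS_CLASSES))]
  }
  # walk representatives in descending identity (ties resolved above)
  # until one offers measurable loop windows; a divergent C-terminus can
  # leave the windows of the single nearest representative unaligned
  ord <- order(-ids, match(vapply(reps, `[[`, "", "gus_class"), GUS_CLASSES))
  ord <- unique(c(tied[1], ord))
  k <- tied[1]
  l1 <- l2 <- NA_integer_
  for (kk in ord) {
    m1 <- measure_loop(alns[[kk]], reps[[kk]]$loop1)
    m2 <- measure_loop(alns[[kk]], reps[[kk]]$loop2)
    if (!is.na(m1) && !is.na(m2)) {
      k <- kk; l1 <- m1; l2 <- m2
      break
    }
    if (kk == tied[1]) { l1 <- m1; l2 <- m2 }
  }
  if (is.na(l1) && is.na(l2)) {
    k <- tied[1]
    return(list(gus_class = reps[[k]]$gus_class, method = "by_nearest",
                ambiguous = ambiguous, nearest_rep = reps[[k]]$id,
                loop1_len = l1, loop2_len = l2))
  }
  v1 <- if (is.na(l1)) 0L else l1
  v2 <- if (is.na(l2)) 0L else l2
  th <- thresholds
  cls <- if (v1 >= th$l1_mini && v2 >= th$l2_mini) {
    if (v1 >= th$l1_long && v2 < th$l2_long) "L1"
    else if (v2 >= th$l2_long && v1 < th$l1_long) "L2"
    else "mL1_2"
  } else if (v1 >= th$l1_long) "L1"
  else if (v1 >= th$l1_mini) "mL1"
  else if (v2 >= th$l2_long) "L2"
  else if (v2 >= th$l2_mini) "mL2"
  else "NL"
  list(gus_class = cls, method = "loop_windows", ambiguous = ambiguous,
       nearest_rep = reps[[k]]$id, loop1_len = l1, loop2_len = l2)
}

#' Assign taxonomy by nearest labelled reference
#'
#' The label of the highest-identity reference is reported together with
#' the identity; below `floor` the label is `"unassigned"`.
#'
#' @param seq amino-acid string.
#' @param reference_db either a `gus_representatives` set (taxonomy labels
#'   are taken from the annotation) or a data.frame with `id`, `seq`,
#'   `taxonomy`.
#' @param floor identity floor, default 0.40.
#' @param params [alignment_params()].
#' @return list with `taxonomy`, `identity`, `reference_id`.
#' @export
assign_taxonomy <- function(seq, reference_db, floor = 0.40,
                            params = alignment_params()) {
  if (inherits(reference_db, "gus_representatives")) {
    reference_db <- data.frame(
      id = vapply(reference_db, `[[`, "", "id"),
      seq = vapply(reference_db, `[[`, "", "seq"),
      taxonomy = vapply(reference_db, `[[`, "", "taxonomy"),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(reference_db) > 0)
  ids <- vapply(reference_db$seq, function(ref) pairwise_identity(seq, ref, params),
                numeric(1))
  best <- which.max(ids)
  if (ids[best] < floor) {
    list(taxonomy = "unassigned", identity = unname(ids[best]),
         reference_id = reference_db$id[best])
  } else {
    list(taxonomy = reference_db$taxonomy[best], identity = unname(ids[best]),
         reference_id = reference_db$id[best])
  }
}

#' Run the full discovery stage on a catalog
#'
#' Screens every candidate, clusters the accepted set at
#' `cluster_threshold`, and annotates each cluster representative with a
#' structural class and taxonomy label.
#'
#' @inheritParams screen_catalog
#' @param cluster_threshold redundancy threshold, default 0.90.
#' @param thresholds [class_thresholds()].
#' @param taxonomy_db reference for [assign_taxonomy()]; defaults to `reps`.
#' @param taxonomy_floor identity floor for taxonomy assignment.
#' @return list with `calls` (screen table) and `clusters` (cluster table
#'   with `gus_class`, `class_method`, `taxonomy`, `taxonomy_identity`).
#' @export
discover_gusome <- function(catalog, reps, threshold = 0.25,
                            cluster_threshold = 0.90,
                            params = alignment_params(),
                            thresholds = class_thresholds(),
                            residue_mode = "best",
                            taxonomy_db = reps, taxonomy_floor = 0.40) {
  gus_log("discover", "screening ", nrow(catalog), " candidates against ",
          length(reps), " representatives")
  calls <- screen_catalog(catalog, reps, threshold, params, residue_mode)
  accepted <- catalog[catalog$id %in% calls$candidate_id[calls$accepted], ,
                      drop = FALSE]
  gus_log("discover", sum(calls$accepted), " accepted; clustering at ",
          cluster_threshold)
  clusters <- cluster_greedy(accepted, cluster_threshold, params)
  if (nrow(clusters) > 0) {
    ann <- lapply(clusters$representative, function(id) {
      s <- accepted$seq[match(id, accepted$id)]
      cl <- assign_class(s, reps, thresholds, params)
      tx <- assign_taxonomy(s, taxonomy_db, taxonomy_floor, params)
      c(cl[c("gus_class", "method")], tx[c("taxonomy", "identity")])
    })
    clusters$gus_class <- vapply(ann, function(a) a$gus_class, "")
    clusters$class_method <- vapply(ann, function(a) a$method, "")
    clusters$taxonomy <- vapply(ann, function(a) a$taxonomy, "")
    clusters$taxonomy_identity <- vapply(ann, function(a) a$identity, 0)
  } else {
    clusters$gus_class <- character(0)
    clusters$class_method <- character(0)
    clusters$taxonomy <- character(0)
    clusters$taxonomy_identity <- numeric(0)
  }
  gus_log("discover", nrow(clusters), " non-redundant GUSome clusters")
  list(calls = calls, clusters = clusters)
}

#' Average-linkage cluster tree on 1 - identity distances
#'
#' Optional Newick export of the GUSome: pairwise aligned-column identities
#' between cluster representatives are converted to distances 1 - identity
#' and clustered by average linkage.
#'
#' @param clusters cluster table from [discover_gusome()].
#' @param catalog the protein catalog (for representative sequences).
#' @param path optional output path for a Newick file (requires the ape
#'   package).
#' @param params [alignment_params()].
#' @return an `hclust` object, invisibly when `path` is given.
#' @export
cluster_tree <- function(clusters, catalog, path = NULL,
                         params = alignment_params()) {
  ids <- clusters$representative
  if (length(ids) < 2) stop("need at least 2 clusters for a tree")
  seqs <- catalog$seq[match(ids, catalog$id)]
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[i], seqs[j], params)
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  if (!is.null(path)) {
    if (!requireNamespace("ape", quietly = TRUE)) {
      warning("ape not available; Newick export skipped")
    } else {
      ape::write.tree(ape::as.phylo(hc), file = path)
    }
    return(invisible(hc))
  }
  hc
}
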