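#' Synthetic cohort generators
#'
#' Generators for a fully labelled synthetic cohort emulating the
#' statistical structure the analysis assumes: a protein catalog with
#' planted GUS genes and decoys, read counts with a planted
#' log10-abundance-vs-length bias, tryptic peptide intensity tables with
#' class-specific group shifts, and MPAG reaction time courses whose true
#' rates depend linearly on planted FMN-class abundance. Every generator
#' is a pure function of its arguments and seed.
#'
#' @name synthetic-cohort
NULL

# typical globular-protein residue frequencies (flat-ish, no C/W excess)
AA_FREQ <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
             I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
             R = 5.5, S = 6.6, T = 5.3, V = 6.9, W = 1.1, Y = 2.9)

random_protein <- function(len) {
  paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

#' Mutate a scaffold to a target pairwise identity
#'
#' Substitution-only mutation (flat over the 19 alternative residues) of a
#' scaffold sequence until its identity to the original, measured with the
#' same local aligner used by discovery, falls within +/- `tol` of
#' `target_identity`. Residues at `preserve` positions are never touched.
#' Because mutated positions are nested (the first k of a fixed random
#' permutation), identity is monotone in the mutation count and a binary
#' search converges. With `indels = TRUE`, short indels (1-4 residues) are
#' additionally placed outside preserved positions to exercise gapped
#' alignment.
#'
#' @param scaffold amino-acid string.
#' @param target_identity fraction in (0, 1].
#' @param preserve integer vector of 1-based positions to keep intact.
#' @param seed integer seed.
#' @param params [alignment_params()] used to measure identity.
#' @param tol acceptance half-width, default 0.02.
#' @param indels also place short indels (default `FALSE`).
#' @return the mutated sequence, with attribute `measured_identity`.
#' @export
mutate_to_identity <- function(scaffold, target_identity, preserve = integer(),
                               seed = 1, params = alignment_params(),
                               tol = 0.02, indels = FALSE) {
  L <- nchar(scaffold)
  stopifnot(target_identity > 0, target_identity <= 1)
  if (any(preserve < 1) || any(preserve > L)) stop("preserve positions invalid")
  floor_id <- length(unique(preserve)) / L
  if (target_identity < floor_id) {
    stop(sprintf("target identity %.3f below achievable floor %.3f given %d preserved positions",
                 target_identity, floor_id, length(unique(preserve))))
  }
  if (target_identity == 1) return(structure(scaffold, measured_identity = 1))
  chars <- strsplit(scaffold, "", fixed = TRUE)[[1]]
  free <- setdiff(seq_len(L), preserve)
  with_seed(seed, {
    perm <- sample(free)
    repl <- vapply(perm, function(i) {
      sample(setdiff(names(AA_FREQ), chars[i]), 1)
    }, character(1))
    indel_plan <- if (indels) {
      k_ind <- max(1, round(L / 150))
      list(pos = sort(sample(free, k_ind)),
           len = sample(1:4, k_ind, replace = TRUE),
           ins = runif(k_ind) < 0.5)
    } else NULL
  })
  build <- function(k) {
    out <- chars
    if (k > 0) out[perm[seq_len(k)]] <- repl[seq_len(k)]
    if (!is.null(indel_plan)) {
      s <- paste(out, collapse = "")
      # apply right-to-left so positions stay valid
      for (i in rev(seq_along(indel_plan$pos))) {
        p <- indel_plan$pos[i]; l <- indel_plan$len[i]
        if (indel_plan$ins[i]) {
          s <- paste0(substr(s, 1, p), strrep("G", l), substr(s, p + 1, nchar(s)))
        } else if (p + l <= nchar(s) &&
                   !any(seq(p, p + l - 1) %in% preserve)) {
          s <- paste0(substr(s, 1, p - 1), substr(s, p + l, nchar(s)))
        }
      }
      return(s)
    }
    paste(out, collapse = "")
  }
  measure <- function(k) pairwise_identity(build(k), scaffold, params)
  lo <- 0L
  hi <- length(perm)
  best_k <- 0L
  best_gap <- abs(measure(0L) - target_identity)
  for (iter in 1:40) {
    k <- as.integer((lo + hi) %/% 2)
    id <- measure(k)
    gap <- abs(id - target_identity)
    if (gap < best_gap) { best_gap <- gap; best_k <- k }
    if (gap <= tol) { best_k <- k; best_gap <- gap; break }
    if (id > target_identity) lo <- k + 1L else hi <- k - 1L
    if (lo > hi) break
  }
  seq_out <- build(best_k)
  id_out <- pairwise_identity(seq_out, scaffold, params)
  if (abs(id_out - target_identity) > tol) {
    warning(sprintf("achieved identity %.3f outside +/-%.2f of target %.3f",
                    id_out, tol, target_identity))
  }
  structure(seq_out, measured_identity = id_out)
}

#' Generate a labelled synthetic protein catalog
#'
#' Plants true GUS genes at identities in `identity_range` (default
#' `[0.35, 0.95]`, clean margins around the 0.25 screen) to class
#' representatives with catalytic residues and their flanks preserved,
#' plus three decoy kinds: `residue_ablated` (GUS-like identity but with
#' 1-3 catalytic residues substituted), `low_identity` (random-composition
#' sequences whose screening identity to every representative is below
#' 0.20), and `random` (composition-shuffled non-homologs).
#'
#' @param n_true named integer vector of true GUS counts per class (names
#'   from [GUS_CLASSES]), or a single unnamed total spread over the
#'   representative classes.
#' @param n_decoys named vector/list with `residue_ablated`,
#'   `low_identity`, `random` counts.
#' @param representatives a `gus_representatives` set.
#' @param seed integer seed.
#' @param identity_range identity band for true GUS.
#' @param ablated_range identity band for residue-ablated decoys.
#' @param conserved_flank residues preserved on each side of a catalytic
#'   position in true GUS (guarantees shared tryptic peptides across genes
#'   of the same representative; default 5).
#' @param params [alignment_params()].
#' @return list with `catalog` (data.frame `id`, `seq`, `length`, `desc`)
#'   and `truth` (data.frame `id`, `is_gus`, `gus_class`, `decoy_kind`,
#'   `source_rep`, `target_identity`, `measured_identity`).
#' @export
generate_catalog <- function(n_true, n_decoys = c(residue_ablated = 0,
                                                  low_identity = 0,
                                                  random = 0),
                             representatives, seed = 1,
                             identity_range = c(0.35, 0.95),
                             ablated_range = c(0.40, 0.90),
                             conserved_flank = 5,
                             params = alignment_params()) {
  stopifnot(length(representatives) > 0)
  if (identity_range[1] > identity_range[2]) stop("impossible identity band")
  n_decoys <- as.list(n_decoys)
  rep_classes <- vapply(representatives, `[[`, "", "gus_class")
  if (is.null(names(n_true))) {
    classes <- unique(rep_classes)
    n_true <- setNames(rep(n_true %/% length(classes) +
                             (seq_along(classes) <= n_true %% length(classes)),
                           1), classes)
  }
  bad <- setdiff(names(n_true)[n_true > 0], rep_classes)
  if (length(bad) > 0) stop("no representative for class(es): ",
                            paste(bad, collapse = ", "))
  rows <- list(); truth <- list()
  add <- function(id, seq, desc, is_gus, cls, kind, src, tgt, meas) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, seq = seq, length = nchar(seq), desc = desc,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- data.frame(
      id = id, is_gus = is_gus, gus_class = cls, decoy_kind = kind,
      source_rep = src, target_identity = tgt, measured_identity = meas,
      stringsAsFactors = FALSE)
  }
  counter <- 0
  next_id <- function() {
    counter <<- counter + 1
    sprintf("gene%04d", counter)
  }
  # Catalytic positions are preserved with short anchor flanks (so the
  # local alignment reliably registers them); the full tryptic-sized
  # flanks only at high identity, where they cannot raise the local
  # aligner's identity floor. FMN-class genes keep every other residue of
  # the FMN-binding segment, emulating a conserved domain that remains
  # recognizable by the FMN classification test.
  preserve_set <- function(rep, target) {
    flank <- if (target >= 0.6) conserved_flank else min(2, conserved_flank)
    pos <- unique(unlist(lapply(rep$cat_pos, function(p) {
      seq(max(1, p - flank), min(nchar(rep$seq), p + flank))
    })))
    if (!is.null(rep$fmn)) {
      pos <- unique(c(pos, seq(rep$fmn[1], rep$fmn[2], by = 2)))
    }
    sort(pos)
  }
  # Clean-margin construction: a GUS-like entry must have its source
  # representative as the best screening hit, otherwise (near the low end
  # of the identity band) the screen's best-hit residue check would run
  # against another subfamily's representative, where catalytic positions
  # need not register. Draws violating this are re-drawn.
  mutate_clean <- function(rep, tgt, sub_seed) {
    for (try in 0:9) {
      seq <- mutate_to_identity(rep$seq, tgt, preserve_set(rep, tgt),
                                seed = sub_seed + try * 1013, params = params)
      ids <- vapply(representatives, function(r)
        screening_identity(align_pair(as.character(seq), r$seq, params),
                           params), numeric(1))
      if (names(representatives)[which.max(ids)] == rep$id) return(seq)
    }
    seq
  }
  # true GUS
  for (cls in names(n_true)) {
    k_cls <- n_true[[cls]]
    if (k_cls == 0) next
    cls_reps <- representatives[rep_classes == cls]
    for (j in seq_len(k_cls)) {
      rep <- cls_reps[[(j - 1) %% length(cls_reps) + 1]]
      sub_seed <- stage_seed(seed, paste0("true_", cls, "_", j))
      tgt <- with_seed(sub_seed, runif(1, identity_range[1], identity_range[2]))
      seq <- mutate_clean(rep, tgt, sub_seed)
      add(next_id(), as.character(seq), paste0("true_gus class=", cls),
          TRUE, cls, NA_character_, rep$id, tgt,
          attr(seq, "measured_identity"))
    }
  }
  # residue-ablated decoys: GUS-like identity, >=1 catalytic residue broken
  n_abl <- n_decoys$residue_ablated %||% 0
  for (j in seq_len(n_abl)) {
    rep <- representatives[[(j - 1) %% length(representatives) + 1]]
    sub_seed <- stage_seed(seed, paste0("ablated_", j))
    tgt <- with_seed(sub_seed, runif(1, ablated_range[1], ablated_range[2]))
    seq <- mutate_clean(rep, tgt, sub_seed)
    chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1]]
    hit <- with_seed(sub_seed + 1,
                     sample(seq_along(rep$cat_pos), sample(1:3, 1)))
    for (h in hit) {
      p <- rep$cat_pos[h]
      chars[p] <- if (chars[p] == "A") "G" else "A"
    }
    add(next_id(), paste(chars, collapse = ""), "decoy kind=residue_ablated",
        FALSE, NA_character_, "residue_ablated", rep$id, tgt,
        attr(seq, "measured_identity"))
  }
  # low-identity decoys: screening identity to every representative < 0.20
  n_low <- n_decoys$low_identity %||% 0
  for (j in seq_len(n_low)) {
    sub_seed <- stage_seed(seed, paste0("low_", j))
    found <- FALSE
    for (try in 1:20) {
      cand <- with_seed(sub_seed + try, random_protein(sample(300:500, 1)))
      ids <- vapply(representatives, function(rep)
        screening_identity(align_pair(cand, rep$seq, params), params),
        numeric(1))
      if (max(ids) < 0.20) { found <- TRUE; break }
    }
    if (!found) stop("could not construct low_identity decoy under the screening-identity rule")
    add(next_id(), cand, "decoy kind=low_identity", FALSE, NA_character_,
        "low_identity", NA_character_, NA_real_, max(ids))
  }
  # random decoys: composition-shuffled representatives
  n_rand <- n_decoys$random %||% 0
  for (j in seq_len(n_rand)) {
    rep <- representatives[[(j - 1) %% length(representatives) + 1]]
    sub_seed <- stage_seed(seed, paste0("random_", j))
    cand <- with_seed(sub_seed, paste(
      sample(strsplit(rep$seq, "", fixed = TRUE)[[1]]), collapse = ""))
    add(next_id(), cand, "decoy kind=random", FALSE, NA_character_,
        "random", rep$id, NA_real_, NA_real_)
  }
  catalog <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  # shuffle catalog order so truth is not encoded in position
  ord <- with_seed(stage_seed(seed, "shuffle"), sample(nrow(catalog)))
  list(catalog = catalog[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Generate a count table with a planted gene-length bias
#'
#' Per-gene baseline log10 abundances are normal around a linear trend in
#' gene length with the planted `bias_slope` (log10 units per residue);
#' per-sample library sizes span at least a two-fold range; counts are
#' Poisson around the expected sampling rates. With `bias_slope = 0` the
#' fitted length-bias slope of the relative counts is 0 within error.
#'
#' @param catalog catalog data.frame (`id`, `length`).
#' @param samples character vector of sample ids.
#' @param bias_slope planted slope, log10 per residue.
#' @param seed integer seed.
#' @param depth expected reads per sample at library factor 1.
#' @param abund_sd sd of the per-gene log10 abundance residual.
#' @return data.frame in count-table layout: `gene_id`, `length`, one
#'   column per sample.
#' @export
generate_counts <- function(catalog, samples, bias_slope = 0.002, seed = 1,
                            depth = 3e5, abund_sd = 0.4) {
  stopifnot(is.finite(bias_slope))
  n_g <- nrow(catalog)
  with_seed(stage_seed(seed, "counts"), {
    base <- rnorm(n_g, 0, abund_sd) +
      bias_slope * (catalog$length - mean(catalog$length))
    w <- 10^base
    w <- w / sum(w)
    # library factors spanning >= 2-fold
    f <- 2^seq(-0.55, 0.55, length.out = length(samples)) *
      exp(rnorm(length(samples), 0, 0.05))
    out <- data.frame(gene_id = catalog$id, length = catalog$length,
                      stringsAsFactors = FALSE)
    for (s in seq_along(samples)) {
      out[[samples[s]]] <- rpois(n_g, depth * f[s] * w)
    }
    out
  })
}

#' Generate a tryptic-peptide intensity table
#'
#' A cohort-level expressed subset of the planted true GUS genes is drawn;
#' per (sample, protein) the log2 protein abundance is
#' `base_log2 + class_effect[class] * (group == shifted_group) + noise`,
#' and the protein's tryptic peptides (cleave after K/R, not before P,
#' length 7-30) receive lognormal intensities that sum to the protein
#' abundance in expectation. Shared peptides across clusters arise from
#' the conserved catalytic flanks planted by [generate_catalog()].
#'
#' @param catalog,truth output of [generate_catalog()].
#' @param metadata data.frame `sample_id`, `group`.
#' @param class_effects named numeric: log2 shift per class applied to
#'   `shifted_group` samples (e.g. `c(FMN = 2)`).
#' @param shifted_group group label receiving the shift (default
#'   `"MMF_recipient"`).
#' @param expressed_fraction fraction of true GUS genes expressed.
#' @param seed integer seed.
#' @param base_log2 baseline log2 protein intensity.
#' @param protein_sd,peptide_sd log2-scale noise sds.
#' @return list with `peptides` (data.frame `sample_id`, `peptide`,
#'   `intensity`), `expressed` (ids), `class_log2` (data.frame
#'   `sample_id`, one column per planted class with the true log2 summed
#'   class intensity).
#' @export
generate_proteome <- function(catalog, truth, metadata,
                              class_effects = c(FMN = 2),
                              shifted_group = "MMF_recipient",
                              expressed_fraction = 0.6, seed = 1,
                              base_log2 = 20, protein_sd = 0.8,
                              peptide_sd = 0.4) {
  gus_ids <- truth$id[truth$is_gus]
  with_seed(stage_seed(seed, "proteome"), {
    n_exp <- max(0, round(expressed_fraction * length(gus_ids)))
    expressed <- if (n_exp > 0) sort(sample(gus_ids, n_exp)) else character(0)
    peps <- list()
    class_sums <- list()  # per sample: named vector of summed class intensity
    for (s in seq_len(nrow(metadata))) {
      sid <- metadata$sample_id[s]
      shift_on <- metadata$group[s] == shifted_group
      class_sum <- setNames(numeric(0), character(0))
      for (pid in expressed) {
        cls <- truth$gus_class[truth$id == pid]
        eff <- if (shift_on && cls %in% names(class_effects))
          class_effects[[cls]] else 0
        m <- base_log2 + eff + rnorm(1, 0, protein_sd)
        seq <- catalog$seq[catalog$id == pid]
        pp <- digest_tryptic(seq)
        if (length(pp) == 0) next
        ints <- 2^m / length(pp) * 2^rnorm(length(pp), 0, peptide_sd)
        peps[[length(peps) + 1]] <- data.frame(
          sample_id = sid, peptide = pp, intensity = ints,
          stringsAsFactors = FALSE)
        class_sum[cls] <- sum(class_sum[cls], sum(ints), na.rm = TRUE)
      }
      class_sums[[sid]] <- class_sum
    }
    peptides <- if (length(peps) > 0) do.call(rbind, peps) else
      data.frame(sample_id = character(), peptide = character(),
                 intensity = numeric(), stringsAsFactors = FALSE)
    classes <- sort(unique(unlist(lapply(class_sums, names))))
    cl_tab <- data.frame(sample_id = metadata$sample_id,
                         stringsAsFactors = FALSE)
    for (cl in classes) {
      v <- vapply(metadata$sample_id, function(sid) {
        tot <- class_sums[[sid]][cl]
        if (!is.na(tot) && tot > 0) log2(tot) else NA_real_
      }, numeric(1))
      cl_tab[[cl]] <- unname(v)
    }
    list(peptides = peptides, expressed = expressed, class_log2 = cl_tab)
  })
}

#' Generate MPAG reaction time courses with planted rates
#'
#' True per-sample rate `r = a + b * fmn + eps`, `eps ~ N(0, noise_sd^2)`,
#' truncated at 0; MPAG declines linearly from `start_nM` with i.i.d.
#' measurement noise per point. The default design mirrors the lysate
#' assay: five endpoints including t = 0, three biological replicates,
#' 400 uM (400,000 nM) starting MPAG.
#'
#' @param fmn_abundance named numeric: per-sample planted log2 FMN-class
#'   intensity (the rate predictor).
#' @param a intercept, nM/s.
#' @param b FMN effect, nM/s per log2-intensity unit.
#' @param noise_sd sd of the rate-level noise, nM/s.
#' @param start_nM starting MPAG concentration (must be positive).
#' @param times_s time points in seconds (default 0/15/30/45/60 min).
#' @param replicates biological replicates per sample (default 3).
#' @param meas_sd measurement noise per point, nM.
#' @param seed integer seed.
#' @return list with `timecourses` (data.frame `sample_id`, `replicate`,
#'   `time_s`, `mpag_nM`) and `truth` (data.frame `sample_id`,
#'   `true_rate_nM_s`).
#' @export
generate_timecourses <- function(fmn_abundance, a = 10, b = 5,
                                 noise_sd = 1, start_nM = 400000,
                                 times_s = c(0, 15, 30, 45, 60) * 60,
                                 replicates = 3, meas_sd = 500, seed = 1) {
  if (start_nM <= 0) stop("starting concentration must be positive")
  stopifnot(length(times_s) >= 2, replicates >= 1)
  samples <- names(fmn_abundance)
  with_seed(stage_seed(seed, "timecourses"), {
    true_rate <- pmax(0, a + b * fmn_abundance + rnorm(length(samples), 0, noise_sd))
    rows <- list()
    for (i in seq_along(samples)) {
      for (r in seq_len(replicates)) {
        conc <- start_nM - true_rate[i] * times_s +
          rnorm(length(times_s), 0, meas_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = samples[i], replicate = r, time_s = times_s,
          mpag_nM = pmax(conc, 0), stringsAsFactors = FALSE)
      }
    }
    list(timecourses = do.call(rbind, rows),
         truth = data.frame(sample_id = samples,
                            fmn = unname(fmn_abundance),
                            true_rate_nM_s = unname(true_rate),
                            stringsAsFactors = FALSE))
  })
}

#' Default cohort metadata: five MMF recipients, four healthy donors
#'
#' @return data.frame `sample_id`, `group`.
#' @export
default_metadata <- function() {
  data.frame(
    sample_id = c(paste0("T", 1:5), paste0("H", 1:4)),
    group = c(rep("MMF_recipient", 5), rep("healthy", 4)),
    stringsAsFactors = FALSE)
}

#' Simulate a complete labelled cohort
#'
#' Chains the generators with a stage-split seed stream and optionally
#' writes the files the pipeline consumes (`catalog.faa`, `truth.tsv`,
#' `counts.tsv`, `peptides.tsv`, `timecourses.tsv`, `metadata.tsv`).
#'
#' @param seed master integer seed.
#' @param representatives representative set (default the bundled
#'   synthetic set).
#' @param n_true,n_decoys catalog composition, see [generate_catalog()].
#' @param bias_slope planted length bias.
#' @param class_effects planted class intensity shifts.
#' @param rate_a,rate_b,rate_noise_sd planted rate-model coefficients.
#' @param metadata cohort metadata (default [default_metadata()]).
#' @param out_dir optional directory to write the files into.
#' @param params [alignment_params()].
#' @param ... further arguments passed to [generate_proteome()].
#' @return list with all generated tables and planted truth.
#' @export
simulate_cohort <- function(seed = 1,
                            representatives = load_default_representatives(),
                            n_true = c(FMN = 6, L1 = 5, mL1 = 4, NL = 5,
                                       L2 = 3, mL2 = 2),
                            n_decoys = c(residue_ablated = 8,
                                         low_identity = 5, random = 8),
                            bias_slope = 0.002,
                            class_effects = c(FMN = 2),
                            rate_a = 10, rate_b = 5, rate_noise_sd = 1,
                            metadata = default_metadata(),
                            out_dir = NULL, params = alignment_params(),
                            ...) {
  gus_log("simulate", "generating catalog (seed ", seed, ")")
  cat_res <- generate_catalog(n_true, n_decoys, representatives, seed,
                              params = params)
  gus_log("simulate", nrow(cat_res$catalog), " catalog entries")
  counts <- generate_counts(cat_res$catalog, metadata$sample_id, bias_slope,
                            seed)
  prot <- generate_proteome(cat_res$catalog, cat_res$truth, metadata,
                            class_effects, seed = seed, ...)
  fmn <- setNames(prot$class_log2$FMN %||% rep(0, nrow(metadata)),
                  prot$class_log2$sample_id)
  fmn[is.na(fmn)] <- 0
  # centered predictor: the rate model's intercept `a` is then the rate of
  # a sample with cohort-average FMN intensity, and rates span a
  # realistic assay range rather than being dominated by the intercept
  fmn <- fmn - mean(fmn)
  tc <- generate_timecourses(fmn, rate_a, rate_b, rate_noise_sd, seed = seed)
  out <- list(metadata = metadata, catalog = cat_res$catalog,
              truth = cat_res$truth, counts = counts,
              peptides = prot$peptides, expressed = prot$expressed,
              class_log2 = prot$class_log2,
              timecourses = tc$timecourses, rate_truth = tc$truth,
              planted = list(bias_slope = bias_slope,
                             class_effects = class_effects,
                             rate_a = rate_a, rate_b = rate_b,
                             rate_noise_sd = rate_noise_sd),
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_fasta(out$catalog, file.path(out_dir, "catalog.faa"))
    write_table(out$truth, file.path(out_dir, "truth.tsv"))
    write_table(out$counts, file.path(out_dir, "counts.tsv"))
    write_table(out$peptides, file.path(out_dir, "peptides.tsv"))
    write_table(out$timecourses, file.path(out_dir, "timecourses.tsv"))
    write_table(out$metadata, file.path(out_dir, "metadata.tsv"))
    gus_log("simulate", "cohort written to ", out_dir)
  }
  out
}
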