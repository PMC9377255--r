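#' Default pipeline configuration
#'
#' One section per stage; values here are the package defaults and mirror
#' the published analysis where it states them (25% identity screen, 90%
#' redundancy clustering). A YAML config file with the same structure can
#' override any subset (see [read_config()]); CLI flags override both.
#'
#' @return nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "gusome_out",
    inputs = list(catalog = NULL, counts = NULL, peptides = NULL,
                  timecourses = NULL, metadata = NULL,
                  representatives_fasta = NULL, representatives_tsv = NULL,
                  taxon_abundance = NULL),
    alignment = list(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1,
                     identity_mode = "aligned", min_coverage = 0.30),
    discover = list(identity_threshold = 0.25, cluster_threshold = 0.90,
                    residue_mode = "best", taxonomy_floor = 0.40,
                    write_tree = FALSE),
    classify = list(l1_long = 12, l1_mini = 5, l2_long = 12, l2_mini = 5,
                    fmn_identity = 0.50),
    diversity = list(shannon_base = 2, n_perm = 999),
    proteomics = list(il_equivalence = TRUE),
    associate = list(reference = "normal", response = "log2_rate",
                     adjust = "none")
  )
}

#' Read a pipeline configuration file
#'
#' Structured text (YAML), one section per stage, merged over
#' [default_config()]: anything not set in the file keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_cfg(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

run_stage <- function(name, fn) {
  tryCatch(fn(), error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full GUSome pipeline
#'
#' Chains discovery, abundance normalization, diversity, proteomics
#' quantification, rate fitting and association testing, writing each
#' stage's tables plus a machine-readable run manifest (config, seed,
#' input checksums) into `config$out_dir`. Rerunning with the same seed
#' and inputs reproduces byte-identical numeric outputs. A stage failure
#' aborts with the stage name; the manifest then flags the run as
#' incomplete.
#'
#' All residue coordinates in outputs are 1-based with closed intervals
#' (stated in each file's comment header).
#'
#' @param config configuration list ([default_config()] /
#'   [read_config()]) with the `inputs` paths filled in.
#' @param stages subset of stages to run (default all, in order).
#' @return list with every stage's in-memory results, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("discover", "abundance", "diversity",
                                    "proteomics", "rates", "associate")) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  al <- config$alignment
  params <- alignment_params(al$matrix, al$gap_open, al$gap_ext,
                             al$identity_mode, al$min_coverage)
  hdr <- "coordinates: 1-based, closed intervals; missing value: '.'"
  manifest <- list(config = config, seed = config$seed,
                   inputs = list(), outputs = character(),
                   stages = list(), complete = FALSE,
                   package_version = as.character(utils::packageVersion("gusome")))
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && file.exists(p)) {
      manifest$inputs[[nm]] <- list(path = p,
                                    md5 = unname(tools::md5sum(p)))
    }
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }
  on.exit(write_manifest())
  emit <- function(df, file, extra = NULL) {
    write_table(df, file.path(out_dir, file), header = c(hdr, extra))
    manifest$outputs <<- c(manifest$outputs, file)
  }
  need <- function(nm) {
    p <- config$inputs[[nm]]
    if (is.null(p) || !file.exists(p)) stop("required input '", nm,
                                            "' missing or unreadable")
    p
  }
  res <- list()

  metadata <- run_stage("io", function()
    read_table(need("metadata"), required = c("sample_id", "group")))
  catalog <- run_stage("io", function() read_protein_fasta(need("catalog")))
  reps <- run_stage("io", function() {
    if (!is.null(config$inputs$representatives_fasta)) {
      read_representatives(need("representatives_fasta"),
                           need("representatives_tsv"))
    } else load_default_representatives()
  })
  res$metadata <- metadata

  if ("discover" %in% stages) {
    res$discovery <- run_stage("discover", function() {
      dc <- config$discover
      th <- do.call(class_thresholds, config$classify)
      disc <- discover_gusome(catalog, reps,
                              threshold = dc$identity_threshold,
                              cluster_threshold = dc$cluster_threshold,
                              params = params, thresholds = th,
                              residue_mode = dc$residue_mode,
                              taxonomy_floor = dc$taxonomy_floor)
      emit(disc$calls, "gus_calls.tsv",
           sprintf("screen: identity > %g (strict), 7/7 catalytic residues",
                   dc$identity_threshold))
      emit(disc$clusters, "gusome_clusters.tsv",
           sprintf("greedy clustering at >= %g identity",
                   dc$cluster_threshold))
      if (isTRUE(dc$write_tree) && nrow(disc$clusters) >= 2) {
        cluster_tree(disc$clusters, catalog,
                     file.path(out_dir, "clusters.nwk"), params)
        manifest$outputs <<- c(manifest$outputs, "clusters.nwk")
      }
      disc
    })
    manifest$stages$discover <- "ok"
  }

  counts <- NULL
  if ("abundance" %in% stages || "diversity" %in% stages) {
    counts <- run_stage("io", function()
      read_table(need("counts"), required = c("gene_id", "length"),
                 numeric_cols = TRUE))
  }

  if ("abundance" %in% stages) {
    res$abundance <- run_stage("abundance", function() {
      ab <- abundance_table(counts)
      tab <- data.frame(gene_id = ab$genes, length = ab$lengths,
                        stringsAsFactors = FALSE)
      for (s in ab$samples) tab[[s]] <- ab$normalized[, s]
      emit(tab, "gene_abundance.tsv",
           sprintf("normalized gene abundance; bias slope %.6g log10/residue; avg length %.2f",
                   ab$slope[1], ab$avg_len))
      if (!is.null(res$discovery)) {
        cab <- class_gene_abundance(ab, res$discovery$clusters)
        emit(cab, "class_abundance.tsv")
        res$class_abundance <<- cab
      }
      ab
    })
    manifest$stages$abundance <- "ok"
  }

  if ("diversity" %in% stages) {
    res$diversity <- run_stage("diversity", function() {
      dv <- config$diversity
      # community profile: taxon table when provided, else raw count
      # proportions over the whole catalog
      if (!is.null(config$inputs$taxon_abundance)) {
        tx <- read_table(need("taxon_abundance"), required = "taxon",
                         numeric_cols = TRUE)
        mat <- as.matrix(tx[, setdiff(names(tx), "taxon"), drop = FALSE])
        rownames(mat) <- tx$taxon
      } else {
        mat <- as.matrix(counts[, setdiff(names(counts),
                                          c("gene_id", "length")),
                                drop = FALSE])
        rownames(mat) <- counts$gene_id
      }
      mat <- mat[, intersect(colnames(mat), metadata$sample_id), drop = FALSE]
      shannon <- vapply(colnames(mat), function(s)
        shannon_index(mat[, s], base = dv$shannon_base), numeric(1))
      emit(data.frame(sample_id = colnames(mat), shannon = shannon,
                      stringsAsFactors = FALSE), "diversity.tsv",
           sprintf("Shannon index, log base %g", dv$shannon_base))
      bc <- bray_curtis_matrix(mat)
      emit(cbind(data.frame(sample_id = rownames(bc)), as.data.frame(bc)),
           "beta.tsv", "Bray-Curtis dissimilarity")
      pc <- pcoa(bc)
      emit(cbind(data.frame(sample_id = rownames(pc$coordinates)),
                 as.data.frame(pc$coordinates)), "pcoa.tsv")
      groups <- metadata$group[match(colnames(mat), metadata$sample_id)]
      pm <- permanova(bc, groups, n_perm = dv$n_perm, seed = config$seed)
      jsonlite::write_json(pm, file.path(out_dir, "permanova.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$outputs <<- c(manifest$outputs, "permanova.json")
      list(shannon = shannon, bray = bc, pcoa = pc, permanova = pm)
    })
    manifest$stages$diversity <- "ok"
  }

  if ("proteomics" %in% stages) {
    res$proteomics <- run_stage("proteomics", function() {
      if (is.null(res$discovery)) stop("discovery results required")
      peps <- read_table(need("peptides"),
                         required = c("sample_id", "peptide", "intensity"),
                         numeric_cols = "intensity")
      mp <- map_peptides(peps, catalog, res$discovery$clusters,
                         config$proteomics$il_equivalence)
      pi <- protein_intensity(mp, res$discovery$clusters)
      emit(pi, "protein_intensity.tsv",
           "summed unique-peptide intensities; undetected proteins absent")
      cov <- coverage_table(mp, res$discovery$clusters, catalog)
      emit(cov, "coverage.tsv", "coverage of cluster representative")
      ci <- class_protein_abundance(pi)
      emit(ci, "class_intensity.tsv", "sum-then-log2 within class")
      gt <- compare_class_intensity(ci, metadata)
      jsonlite::write_json(gt, file.path(out_dir, "group_tests.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "rows")
      manifest$outputs <<- c(manifest$outputs, "group_tests.json")
      list(mapped = mp, protein = pi, coverage = cov, class_intensity = ci,
           group_tests = gt)
    })
    manifest$stages$proteomics <- "ok"
  }

  if ("rates" %in% stages) {
    res$rates <- run_stage("rates", function() {
      tc <- read_table(need("timecourses"),
                       required = c("sample_id", "replicate", "time_s",
                                    "mpag_nM"),
                       numeric_cols = c("replicate", "time_s", "mpag_nM"))
      rt <- fit_rates(tc)
      emit(rt, "rates.tsv",
           "reactivation rate = |OLS slope| of MPAG vs time, nM/s; mean of replicates; log2 of mean")
      rt
    })
    manifest$stages$rates <- "ok"
  }

  if ("associate" %in% stages) {
    res$associations <- run_stage("associate", function() {
      if (is.null(res$rates)) stop("rate results required")
      ac <- config$associate
      preds <- NULL
      if (!is.null(res$proteomics)) {
        preds <- predictor_matrix(res$proteomics$class_intensity)
      }
      if (!is.null(res$class_abundance)) {
        mg <- predictor_matrix(res$class_abundance, value = "abundance",
                               total = TRUE)
        names(mg)[-1] <- paste0("gene_", names(mg)[-1])
        preds <- if (is.null(preds)) mg else
          merge(preds, mg, by = "sample_id", all = TRUE)
      }
      if (is.null(preds)) stop("no predictors available")
      assoc <- associate_rates(res$rates, preds, response = ac$response,
                               reference = ac$reference,
                               adjust = ac$adjust)
      emit(assoc, "associations.tsv",
           sprintf("Wald slope test, %s reference", ac$reference))
      assoc
    })
    manifest$stages$associate <- "ok"
  }

  manifest$complete <- TRUE
  gus_log("pipeline", "done; outputs in ", out_dir)
  invisible(res)
}
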