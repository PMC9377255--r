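#' Relative count of a gene in a sample
#'
#' Library-size scaling of raw read counts to a log10 scale:
#' \deqn{RelativeCount = \log_{10}\!\left[\left(
#'   \frac{GeneReadCount}{TotalAssignedReadsInSample} \times
#'   \frac{TotalAssignedReadsAcrossAllSamples}{NumberOfSamples}\right)
#'   + 1\right]}
#' A count of 0 maps exactly to 0; the transform is strictly increasing in
#' the count.
#'
#' @param count raw gene read count (non-negative integer, vectorized).
#' @param total_in_sample total assigned reads in the sample.
#' @param total_all total assigned reads across all samples.
#' @param n_samples number of samples.
#' @return relative count(s) on the log10 scale.
#' @export
relative_count <- function(count, total_in_sample, total_all, n_samples) {
  stopifnot(n_samples > 0, all(count >= 0))
  if (total_in_sample == 0) {
    if (any(count > 0)) stop("count > 0 with zero total assigned reads")
    return(rep(0, length(count)))
  }
  if (any(count > total_in_sample)) {
    stop("gene count exceeds total assigned reads in sample")
  }
  log10(count / total_in_sample * total_all / n_samples + 1)
}

#' Fit the gene-length bias of relative counts
#'
#' Ordinary least squares of relative count on gene length, pooled over all
#' (gene, sample) pairs. The slope is in log10 units per length unit.
#'
#' @param rel_counts numeric vector of relative counts.
#' @param lengths matching gene lengths.
#' @return list with `slope`, `intercept`, `slope_se`.
#' @export
fit_length_bias <- function(rel_counts, lengths) {
  ok <- is.finite(rel_counts) & is.finite(lengths)
  rel_counts <- rel_counts[ok]
  lengths <- lengths[ok]
  if (length(rel_counts) < 3) stop("need at least 3 points")
  if (length(unique(lengths)) < 2) stop("degenerate design: lengths all equal")
  fit <- lm(rel_counts ~ lengths)
  beta <- unname(coef(fit))
  rss <- sum(fit$residuals^2)
  sxx <- sum((lengths - mean(lengths))^2)
  list(slope = beta[2], intercept = beta[1],
       slope_se = sqrt(rss / (length(lengths) - 2) / sxx))
}

#' Length-bias-corrected normalized gene abundance
#'
#' \deqn{NormalizedGeneAbundance = RelativeCount +
#'   Slope \times (AverageGeneLength - GeneLength)}
#' When the slope comes from the pooled OLS fit and `avg_len` is the mean
#' gene length, regressing the normalized abundances back on length gives a
#' slope of exactly zero (algebraic de-biasing identity).
#'
#' @param rel_count relative count(s), log10 scale.
#' @param slope fitted bias slope.
#' @param avg_len average gene length over the cohort.
#' @param len gene length(s).
#' @return normalized abundance(s).
#' @export
normalize_abundance <- function(rel_count, slope, avg_len, len) {
  stopifnot(is.finite(slope), is.finite(avg_len))
  rel_count + slope * (avg_len - len)
}

#' Build the full abundance table from a count table
#'
#' Takes a gene x sample count table (columns `gene_id`, `length`, then one
#' column per sample), computes per-sample relative counts, fits the pooled
#' length-bias regression, and applies the correction.
#'
#' @param counts data.frame with `gene_id`, `length` and sample columns.
#' @param per_sample_slope fit one slope per sample instead of the pooled
#'   cohort slope (default `FALSE`, matching the single published slope).
#' @return list of class `gus_abundance`: `genes` (ids), `lengths`,
#'   `samples`, `raw` / `relative` / `normalized` (gene x sample matrices),
#'   `slope`, `slope_se`, `avg_len`, `totals` (per-sample assigned reads).
#' @export
abundance_table <- function(counts, per_sample_slope = FALSE) {
  req <- c("gene_id", "length")
  stopifnot(all(req %in% names(counts)))
  samples <- setdiff(names(counts), req)
  if (length(samples) == 0) stop("no sample columns in count table")
  raw <- as.matrix(counts[, samples, drop = FALSE])
  storage.mode(raw) <- "double"
  if (any(raw < 0)) stop("negative counts")
  rownames(raw) <- counts$gene_id
  lengths <- counts$length
  totals <- colSums(raw)
  total_all <- sum(totals)
  n <- length(samples)
  rel <- raw
  for (s in seq_len(n)) {
    rel[, s] <- relative_count(raw[, s], totals[s], total_all, n)
  }
  avg_len <- mean(lengths)
  if (per_sample_slope) {
    norm <- rel
    slopes <- numeric(n)
    for (s in seq_len(n)) {
      f <- fit_length_bias(rel[, s], lengths)
      slopes[s] <- f$slope
      norm[, s] <- normalize_abundance(rel[, s], f$slope, avg_len, lengths)
    }
    slope <- slopes
    slope_se <- NA_real_
  } else {
    f <- fit_length_bias(as.vector(rel), rep(lengths, n))
    slope <- f$slope
    slope_se <- f$slope_se
    norm <- rel + slope * (avg_len - lengths)
  }
  structure(list(genes = counts$gene_id, lengths = lengths,
                 samples = samples, raw = raw, relative = rel,
                 normalized = norm, slope = slope, slope_se = slope_se,
                 avg_len = avg_len, totals = totals),
            class = "gus_abundance")
}

#' @export
print.gus_abundance <- function(x, ...) {
  cat(sprintf("abundance table: %d genes x %d samples, bias slope %.3g (log10/residue)\n",
              length(x$genes), length(x$samples), x$slope[1]))
  invisible(x)
}

#' Per-class summed normalized gene abundance
#'
#' Normalized abundances of all member genes of each cluster are mapped to
#' the cluster's structural class and summed per sample. Classes absent in
#' a sample are reported as 0.
#'
#' @param ab a [abundance_table()] result.
#' @param clusters cluster table from [discover_gusome()] (needs `members`
#'   and `gus_class`).
#' @return data.frame: one row per (class, sample) with `gus_class`,
#'   `sample_id`, `abundance`.
#' @export
class_gene_abundance <- function(ab, clusters) {
  member_ids <- strsplit(clusters$members, ",", fixed = TRUE)
  unknown <- setdiff(unlist(member_ids), ab$genes)
  if (length(unknown) > 0) {
    stop("cluster member(s) absent from abundance table: ",
         paste(head(unknown, 3), collapse = ", "))
  }
  classes <- sort(unique(clusters$gus_class))
  out <- expand.grid(gus_class = classes, sample_id = ab$samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$abundance <- 0
  for (k in seq_len(nrow(clusters))) {
    rows <- match(member_ids[[k]], ab$genes)
    vals <- colSums(ab$normalized[rows, , drop = FALSE])
    sel <- out$gus_class == clusters$gus_class[k]
    out$abundance[sel] <- out$abundance[sel] +
      vals[match(out$sample_id[sel], ab$samples)]
  }
  out
}
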