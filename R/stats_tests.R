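#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with the Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs are resolved explicitly rather than erroring: when
#' both groups have zero variance, equal means give `t = 0, p = 1` and
#' different means give `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @return list with `t`, `df`, `p`, `mean_diff` (`mean(x) - mean(y)`),
#'   `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0,
                mean_diff = mean(x) - mean(y), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(x) - mean(y), degenerate = FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped; ranks of |differences| use midranks for
#' ties. For `n <= exact_limit` pairs the two-sided p-value is exact, by
#' full enumeration of all 2^n sign assignments of the observed ranks
#' (valid under ties); otherwise the normal approximation with tie
#' correction is used.
#'
#' @param x,y paired numeric vectors of equal length; at least 3 non-zero
#'   differences required.
#' @param exact_limit largest n for exact enumeration (default 15).
#' @return list with `W` (min of the signed-rank sums), `W_plus`,
#'   `W_minus`, `p` (two-sided), `n` (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 15) {
  if (length(x) != length(y)) stop("paired vectors of unequal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences zero")
  if (n < 3) stop("fewer than 3 non-zero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    # distribution of W+ over all sign assignments of the observed ranks
    signs <- expand.grid(rep(list(c(0, 1)), n))
    wdist <- as.matrix(signs) %*% r
    lo <- min(w_plus, w_minus)
    hi <- max(w_plus, w_minus)
    p <- (sum(wdist <= lo) + sum(wdist >= hi)) / 2^n
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(W = w, W_plus = w_plus, W_minus = w_minus, p = min(p, 1), n = n,
       method = method)
}

#' Group comparisons of class-level intensities
#'
#' Welch's t-test of log2 class intensity between the two cohort groups,
#' one test per structural class. Classes absent in a sample are treated
#' as missing (not zero); a sensitivity mode substitutes a floor value for
#' absent classes.
#'
#' @param class_intensity [class_protein_abundance()] output.
#' @param metadata data.frame with `sample_id`, `group` (two levels).
#' @param floor optional log2 floor substituted for absent (class, sample)
#'   pairs; `NULL` (default) leaves them missing.
#' @return data.frame: `gus_class`, `n1`, `n2`, `t`, `df`, `p` (NA when a
#'   group has fewer than 2 detected samples).
#' @export
compare_class_intensity <- function(class_intensity, metadata, floor = NULL) {
  groups <- sort(unique(metadata$group))
  if (length(groups) != 2) stop("metadata must contain exactly 2 groups")
  out <- list()
  for (cl in sort(unique(class_intensity$gus_class))) {
    sub <- class_intensity[class_intensity$gus_class == cl, , drop = FALSE]
    vals <- setNames(sub$log2_intensity, sub$sample_id)
    if (!is.null(floor)) {
      missing <- setdiff(metadata$sample_id, names(vals))
      vals <- c(vals, setNames(rep(floor, length(missing)), missing))
    }
    g <- metadata$group[match(names(vals), metadata$sample_id)]
    x <- vals[g == groups[1]]
    y <- vals[g == groups[2]]
    if (length(x) >= 2 && length(y) >= 2) {
      wt <- welch_t(x, y)
      row <- data.frame(gus_class = cl, n1 = length(x), n2 = length(y),
                        t = wt$t, df = wt$df, p = wt$p,
                        stringsAsFactors = FALSE)
    } else {
      row <- data.frame(gus_class = cl, n1 = length(x), n2 = length(y),
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}
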