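#' Fit an MPAG reactivation rate from a time course
#'
#' Per replicate, MPAG concentration is fit to time by ordinary least
#' squares. The assay tracks MPAG disappearance, so the reactivation rate
#' is the magnitude of the (negative) slope; a rising-MPAG fit is flagged
#' and its rate reported as 0 with a warning. Replicate rates are averaged
#' (SEM = sd/sqrt(k)) and the mean is log2-transformed.
#'
#' @param tc data.frame for one sample: columns `replicate`, `time_s`
#'   (seconds), `mpag_nM`.
#' @return list with `replicate_rates` (nM/s), `rate` (mean), `sem`,
#'   `log2_rate` (NA unless mean > 0), `r_squared` (per replicate),
#'   `flagged_rising` (logical per replicate).
#' @export
fit_rate <- function(tc) {
  stopifnot(all(c("replicate", "time_s", "mpag_nM") %in% names(tc)))
  reps <- sort(unique(tc$replicate))
  rates <- numeric(length(reps))
  r2 <- numeric(length(reps))
  rising <- logical(length(reps))
  for (i in seq_along(reps)) {
    sub <- tc[tc$replicate == reps[i], , drop = FALSE]
    if (length(unique(sub$time_s)) < 2) stop("zero time-variance in replicate ",
                                             reps[i])
    fit <- lm(mpag_nM ~ time_s, data = sub)
    slope <- unname(coef(fit)[2])
    if (slope > 0) {
      warning("rising MPAG in replicate ", reps[i], "; rate reported as 0")
      rising[i] <- TRUE
      rates[i] <- 0
    } else {
      rates[i] <- -slope
    }
    ss_tot <- sum((sub$mpag_nM - mean(sub$mpag_nM))^2)
    r2[i] <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  }
  mean_rate <- mean(rates)
  sem <- if (length(rates) > 1) sd(rates) / sqrt(length(rates)) else 0
  list(replicate_rates = setNames(rates, reps), rate = mean_rate, sem = sem,
       log2_rate = if (mean_rate > 0) log2(mean_rate) else NA_real_,
       r_squared = setNames(r2, reps), flagged_rising = setNames(rising, reps))
}

#' Fit rates for every sample in a time-course table
#'
#' @param timecourses data.frame with `sample_id`, `replicate`, `time_s`,
#'   `mpag_nM`.
#' @return data.frame: `sample_id`, `rate_nM_s`, `sem`, `log2_rate`,
#'   `n_replicates`, `min_r2`.
#' @export
fit_rates <- function(timecourses) {
  ids <- unique(timecourses$sample_id)
  rows <- lapply(ids, function(s) {
    f <- fit_rate(timecourses[timecourses$sample_id == s, , drop = FALSE])
    data.frame(sample_id = s, rate_nM_s = f$rate, sem = f$sem,
               log2_rate = f$log2_rate,
               n_replicates = length(f$replicate_rates),
               min_r2 = min(f$r_squared), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Specific activity from a product time course
#'
#' Initial-rate estimation for a purified-enzyme assay: the best-fit
#' contiguous window of at least `max(3, ceil(0.25 n))` points maximizing
#' r-squared is selected (earliest window wins ties, biasing to the
#' initial linear phase), its slope magnitude (nM/s) is divided by the
#' enzyme concentration to give specific activity in 1/s.
#'
#' @param time_s time points, seconds.
#' @param product_nM product signal in nM (apply any calibration factor
#'   before calling).
#' @param enzyme_conc_nM enzyme concentration, nM, positive.
#' @param r2_floor minimum acceptable window r-squared (default 0.8).
#' @return list with `specific_activity` (1/s), `slope_nM_s`, `window`
#'   (indices), `r_squared`.
#' @export
specific_activity <- function(time_s, product_nM, enzyme_conc_nM,
                              r2_floor = 0.8) {
  if (enzyme_conc_nM <= 0) stop("enzyme concentration must be positive")
  n <- length(time_s)
  stopifnot(length(product_nM) == n, n >= 3)
  ord <- order(time_s)
  time_s <- time_s[ord]; product_nM <- product_nM[ord]
  min_len <- max(3, ceiling(0.25 * n))
  best <- NULL
  for (start in seq_len(n - min_len + 1)) {
    for (end in seq(start + min_len - 1, n)) {
      tt <- time_s[start:end]; yy <- product_nM[start:end]
      if (length(unique(tt)) < 2) next
      fit <- lm.fit(cbind(1, tt), yy)
      ss_tot <- sum((yy - mean(yy))^2)
      r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 0
      if (is.null(best) || r2 > best$r2 + 1e-12) {
        best <- list(r2 = r2, slope = unname(fit$coefficients[2]),
                     window = c(start, end))
      }
    }
  }
  if (is.null(best) || best$r2 < r2_floor) stop("no linear phase")
  list(specific_activity = abs(best$slope) / enzyme_conc_nM,
       slope_nM_s = unname(best$slope), window = best$window,
       r_squared = best$r2)
}

#' Wald test for a non-zero regression slope
#'
#' OLS of `y` on `x`; the Wald statistic is the slope over its standard
#' error, referred to the standard normal by default (a t(n-2) reference
#' is available, matching common graphing software). An exact linear fit
#' (zero residual) is reported as `p = 0` with `exact_fit = TRUE`.
#'
#' @param x predictor values (not constant).
#' @param y response values; `n >= 3`.
#' @param reference `"normal"` (default) or `"t"`.
#' @return list of class `gus_association`: `slope`, `se`, `statistic`,
#'   `p`, `n`, `reference`, `exact_fit`.
#' @export
wald_slope_test <- function(x, y, reference = c("normal", "t")) {
  reference <- match.arg(reference)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2) stop("constant predictor")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- sum(xc * y) / sxx
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-12 * max(tss, 1e-300)) {
    return(structure(list(slope = beta, se = 0, statistic = Inf, p = 0,
                          n = n, reference = reference, exact_fit = TRUE),
                     class = "gus_association"))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  z <- beta / se
  p <- if (reference == "normal") 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), n - 2)
  structure(list(slope = beta, se = se, statistic = z, p = p, n = n,
                 reference = reference, exact_fit = FALSE),
            class = "gus_association")
}

#' @export
print.gus_association <- function(x, ...) {
  cat(sprintf("Wald slope test (%s): slope %.4g (se %.4g), z %.3f, p %.4g, n %d\n",
              x$reference, x$slope, x$se, x$statistic, x$p, x$n))
  invisible(x)
}

#' Associate reactivation rates with abundance predictors
#'
#' One Wald slope test per predictor column: rate (log2 by default) as
#' response, predictor abundance as x. Predictors with fewer than 3 shared
#' non-missing samples are skipped with a warning. No multiplicity
#' adjustment is applied by default; Benjamini-Hochberg is available.
#'
#' @param rates [fit_rates()] output.
#' @param predictors data.frame with `sample_id` and one numeric column
#'   per predictor (e.g. per-class log2 intensities; see
#'   [predictor_matrix()]).
#' @param response `"log2_rate"` (default) or `"rate_nM_s"`.
#' @param reference Wald reference distribution, see [wald_slope_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `predictor`, `slope`, `se`, `statistic`, `p`,
#'   (`p_adj` when adjusted), `n`.
#' @export
associate_rates <- function(rates, predictors, response = "log2_rate",
                            reference = "normal", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot("sample_id" %in% names(predictors))
  pred_cols <- setdiff(names(predictors), "sample_id")
  rows <- list()
  for (pc in pred_cols) {
    m <- match(rates$sample_id, predictors$sample_id)
    x <- predictors[[pc]][m]
    y <- rates[[response]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warning("predictor '", pc, "' skipped: fewer than 3 shared samples")
      next
    }
    wt <- wald_slope_test(x[ok], y[ok], reference)
    rows[[length(rows) + 1]] <- data.frame(
      predictor = pc, slope = wt$slope, se = wt$se, statistic = wt$statistic,
      p = wt$p, n = wt$n, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(predictor = character(), slope = numeric(), se = numeric(),
               statistic = numeric(), p = numeric(), n = integer(),
               stringsAsFactors = FALSE)
  if (adjust == "BH" && nrow(out) > 0) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Widen a long (class, sample, value) table into a predictor matrix
#'
#' @param long data.frame with a key column, `sample_id` and a value
#'   column.
#' @param key,value column names (defaults `gus_class`, `log2_intensity`).
#' @param total add a `total` column: log2 of the per-sample sum of raw
#'   intensities when `value` is a log2 column, else the plain sum.
#' @return data.frame with `sample_id` and one column per key level.
#' @export
predictor_matrix <- function(long, key = "gus_class",
                             value = "log2_intensity", total = TRUE) {
  samples <- sort(unique(long$sample_id))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (k in sort(unique(long[[key]]))) {
    sub <- long[long[[key]] == k, , drop = FALSE]
    out[[k]] <- sub[[value]][match(samples, sub$sample_id)]
  }
  if (total) {
    is_log2 <- grepl("log2", value, fixed = TRUE)
    raw_col <- if (is_log2 && "intensity" %in% names(long)) "intensity" else value
    tot <- vapply(samples, function(s)
      sum(long[[raw_col]][long$sample_id == s], na.rm = TRUE), numeric(1))
    out$total <- if (is_log2) ifelse(tot > 0, log2(tot), NA_real_) else tot
  }
  out
}

#' Scatter plot of reactivation rate against a predictor
#'
#' Rate (log2 by default) against one abundance predictor with the OLS
#' line and the Wald p-value annotated, in the style of a
#' rate-vs-abundance correlation panel.
#'
#' @param rates [fit_rates()] output.
#' @param predictors predictor table as in [associate_rates()].
#' @param predictor name of the predictor column to plot.
#' @param response `"log2_rate"` (default) or `"rate_nM_s"`.
#' @param reference Wald reference distribution.
#' @param ... further arguments to [plot()].
#' @return the [wald_slope_test()] result, invisibly.
#' @export
plot_rate_association <- function(rates, predictors, predictor,
                                  response = "log2_rate",
                                  reference = "normal", ...) {
  stopifnot(predictor %in% names(predictors))
  x <- predictors[[predictor]][match(rates$sample_id, predictors$sample_id)]
  y <- rates[[response]]
  ok <- is.finite(x) & is.finite(y)
  wt <- wald_slope_test(x[ok], y[ok], reference)
  ylab <- if (response == "log2_rate") "log2 reactivation rate (nM/s)"
  else "reactivation rate (nM/s)"
  plot(x[ok], y[ok], pch = 19, xlab = paste(predictor, "abundance"),
       ylab = ylab, ...)
  graphics::abline(a = mean(y[ok]) - wt$slope * mean(x[ok]), b = wt$slope)
  graphics::mtext(sprintf("slope = %.3g, P = %.3g (Wald, n = %d)",
                          wt$slope, wt$p, wt$n), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(wt)
}
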