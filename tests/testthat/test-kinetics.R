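test_that("rate fitting is exact on a noiseless decline", {
  t <- c(0, 15, 30, 45, 60) * 60
  tc <- data.frame(replicate = 1, time_s = t, mpag_nM = 400000 - 5 * t)
  f <- fit_rate(tc)
  expect_equal(f$rate, 5, tolerance = 1e-12)
  expect_equal(unname(f$r_squared), 1)
  expect_equal(f$log2_rate, log2(5))

  flat <- data.frame(replicate = 1, time_s = t, mpag_nM = rep(1000, 5))
  expect_equal(fit_rate(flat)$rate, 0)
})

test_that("replicate rates average with the stated SEM", {
  t <- c(0, 900, 1800)
  tc <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(replicate = r, time_s = t, mpag_nM = 1e5 - c(3, 4, 5)[r] * t)
  }))
  f <- fit_rate(tc)
  expect_equal(f$replicate_rates, c(`1` = 3, `2` = 4, `3` = 5))
  expect_equal(f$rate, 4)
  expect_equal(f$sem, 0.5774, tolerance = 1e-4)
})

test_that("rising MPAG is flagged and reported as rate 0", {
  t <- c(0, 900, 1800)
  tc <- data.frame(replicate = 1, time_s = t, mpag_nM = 100 + 2 * t)
  expect_warning(f <- fit_rate(tc), "rising")
  expect_equal(f$rate, 0)
  expect_true(f$flagged_rising[[1]])
  bad <- data.frame(replicate = 1, time_s = c(5, 5, 5), mpag_nM = c(1, 2, 3))
  expect_error(fit_rate(bad), "time-variance")
})

test_that("specific activity divides the initial-rate slope by enzyme", {
  t <- seq(0, 120, by = 15)
  sa <- specific_activity(t, 2 * t, enzyme_conc_nM = 100)
  expect_equal(sa$specific_activity, 0.02, tolerance = 1e-12)
  expect_error(specific_activity(t, 2 * t, 0), "positive")
  # homogeneity: doubling the enzyme halves the result
  sa2 <- specific_activity(t, 2 * t, 200)
  expect_equal(sa2$specific_activity, sa$specific_activity / 2)
})

test_that("window selection recovers the early linear phase of a plateau", {
  t <- seq(0, 200, by = 10)
  y <- pmin(3 * t, 300)  # linear to t = 100, then flat
  sa <- specific_activity(t, y, 100)
  expect_lt(abs(sa$slope_nM_s - 3) / 3, 0.05)
  expect_error(specific_activity(c(0, 1, 2, 3),
                                 c(0, 10, -10, 5), 10, r2_floor = 0.99),
               "no linear phase")
})

test_that("Wald slope test matches hand OLS and flags exact fits", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  w <- wald_slope_test(x, y)
  expect_equal(w$slope, 2.3)
  # closed-form OLS se computed by hand
  beta <- 2.3; alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / 2 / sum((x - mean(x))^2))
  expect_equal(w$se, se, tolerance = 1e-12)
  expect_equal(w$p, 2 * pnorm(-abs(beta / se)), tolerance = 1e-12)

  wx <- wald_slope_test(1:5, 3 * (1:5) + 1)
  expect_true(wx$exact_fit)
  expect_equal(wx$p, 0)
  expect_error(wald_slope_test(rep(2, 4), 1:4), "constant")
  expect_error(wald_slope_test(1:2, 1:2), "at least 3")
})

test_that("Wald p is invariant to affine rescaling of x and y", {
  set.seed(501)
  x <- rnorm(9); y <- 0.5 * x + rnorm(9)
  p0 <- wald_slope_test(x, y)$p
  expect_equal(wald_slope_test(10 * x + 3, y)$p, p0, tolerance = 1e-10)
  expect_equal(wald_slope_test(x, -2 * y + 7)$p, p0, tolerance = 1e-10)
  # t-reference mode gives the lm summary p-value
  wt <- wald_slope_test(x, y, reference = "t")
  ref <- summary(lm(y ~ x))$coefficients[2, 4]
  expect_equal(wt$p, ref, tolerance = 1e-10)
})

test_that("association scan tests each predictor and skips sparse ones", {
  set.seed(502)
  rates <- data.frame(sample_id = paste0("S", 1:8),
                      rate_nM_s = 2^seq(1, 4, length.out = 8),
                      log2_rate = seq(1, 4, length.out = 8),
                      stringsAsFactors = FALSE)
  preds <- data.frame(sample_id = rates$sample_id,
                      good = seq(1, 4, length.out = 8) + rnorm(8, 0, 0.1),
                      sparse = c(1, 2, rep(NA, 6)),
                      stringsAsFactors = FALSE)
  expect_warning(out <- associate_rates(rates, preds), "sparse")
  expect_equal(out$predictor, "good")
  expect_lt(out$p, 0.01)
  out_bh <- suppressWarnings(associate_rates(rates, preds, adjust = "BH"))
  expect_true("p_adj" %in% names(out_bh))
})

test_that("predictor_matrix widens class intensities with a total column", {
  long <- data.frame(gus_class = c("FMN", "FMN", "NL"),
                     sample_id = c("S1", "S2", "S1"),
                     intensity = c(8, 4, 8),
                     log2_intensity = c(3, 2, 3),
                     stringsAsFactors = FALSE)
  w <- predictor_matrix(long)
  expect_equal(w$FMN, c(3, 2))
  expect_true(is.na(w$NL[2]))
  expect_equal(w$total, c(log2(16), 2))
})
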