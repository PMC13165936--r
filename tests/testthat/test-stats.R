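test_that("median-IQR summaries reproduce the printed cohort values", {
  tc <- tolerance_cohort()
  mm <- summarize_median_iqr(tc$mm_current_ma)
  expect_equal(c(mm$median, mm$q1, mm$q3), c(240, 215, 250))
  mn <- summarize_median_iqr(tc$mn_current_ma)
  expect_equal(c(mn$median, mn$q1, mn$q3), c(235, 120, 240))
  vas <- summarize_median_iqr(tc$mn_vas)
  expect_equal(c(vas$median, vas$q1, vas$q3), c(7, 7, 8))
  # exclusive-halves rule on a simple odd-n vector
  s <- summarize_median_iqr(1:5)
  expect_equal(c(s$median, s$q1, s$q3), c(3, 1.5, 4.5))
  expect_error(summarize_median_iqr(c(1, 2)), class = "pupilkit_contract_error")
})

test_that("exact Wilcoxon reproduces the cohort paired tests", {
  tc <- tolerance_cohort()
  vas <- wilcoxon_signed_rank(tc$mn_vas, tc$mm_vas)
  expect_equal(vas$n_effective, 8L)
  expect_equal(vas$w_statistic, 0)
  expect_equal(vas$p_two_sided, 2 / 256)
  expect_identical(vas$method, "exact")

  cur <- wilcoxon_signed_rank(tc$mn_current_ma, tc$mm_current_ma)
  expect_equal(cur$n_effective, 6L)
  expect_equal(cur$p_two_sided, 0.0625)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), class = "pupilkit_degenerate_error")
})

test_that("exact Wilcoxon equals brute-force sign enumeration on random data", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    x <- sample(0:10, n, replace = TRUE)   # integer data: plenty of ties/zeros
    y <- sample(0:10, n, replace = TRUE)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_two_sided, oracle_wilcoxon_p(x, y))
  }
})

test_that("large-sample Wilcoxon falls back to a tie-corrected normal approximation", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  res <- wilcoxon_signed_rank(x, y)
  expect_identical(res$method, "normal-approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman correlation handles monotone, tied and degenerate inputs", {
  x <- c(0.3, 1.2, 2.2, 3.9, 5.1)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  # mid-rank rho equals Pearson on mid-ranks
  xs <- c(1, 2, 2, 3); ys <- c(1, 3, 2, 4)
  got <- spearman_rho(xs, ys)
  expect_equal(got$rho, stats::cor(rank(xs), rank(ys)))
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "pupilkit_degenerate_error")
  # untied small-n p matches the exact reference distribution
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(spearman_rho(a, b)$p,
               stats::cor.test(a, b, method = "spearman", exact = TRUE)$p.value)
})

test_that("Shapiro-Wilk gate behaves on near-normal, bimodal and constant input", {
  z <- qnorm(ppoints(20))
  expect_gt(shapiro_wilk(z)$W, 0.99)
  bimodal <- rep(c(-1, 1), each = 10) + seq(-0.01, 0.01, length.out = 20)
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)
  expect_error(shapiro_wilk(rep(3, 10)), class = "pupilkit_contract_error")
  expect_error(shapiro_wilk(c(1, 2)), class = "pupilkit_contract_error")
})

test_that("non-parametric agreement report summarises paired differences", {
  m2 <- rnorm(10)
  # identical methods: zero bias everywhere, perfect rank agreement
  rep0 <- bland_altman_nonparametric(m2, m2)
  expect_equal(c(rep0$bias_median, rep0$bias_q1, rep0$bias_q3,
                 rep0$loa_low, rep0$loa_high), rep(0, 5))
  expect_equal(rep0$spearman_rho, 1)
  # constant methods: correlation genuinely undefined, reported missing
  expect_warning(repc <- bland_altman_nonparametric(rep(2, 5), rep(1, 5)),
                 "undefined")
  expect_true(is.na(repc$spearman_rho))
  expect_equal(repc$bias_median, 1)
  # constant offset
  rep2 <- bland_altman_nonparametric(m2 + 2, m2)
  expect_equal(c(rep2$bias_median, rep2$loa_low, rep2$loa_high), c(2, 2, 2))
  # fabricated differences: percentiles match order-statistics oracle
  d <- c(-3, -2, -1, 0, 0, 1, 1, 2, 3, 4)
  rep3 <- suppressWarnings(bland_altman_nonparametric(d, rep(0, 10)))
  expect_equal(rep3$loa_low, -3 + 0.225 * 1)    # type-7 h = 1.225
  expect_equal(rep3$loa_high, 3 + 0.775 * 1)    # type-7 h = 9.775
  expect_equal(rep3$bias_median, 0.5)
  # antisymmetry under swapping the methods
  set.seed(31)
  a <- rnorm(25); b <- rnorm(25)
  r1 <- bland_altman_nonparametric(a, b)
  r2 <- bland_altman_nonparametric(b, a)
  expect_equal(r1$bias_median, -r2$bias_median)
  expect_equal(r1$loa_low, -r2$loa_high)
  expect_equal(r1$loa_high, -r2$loa_low)
  expect_error(bland_altman_nonparametric(1:3, 1:3),
               class = "pupilkit_insufficient_data_error")
})

test_that("pupillary response averages normalised area before converting to mm", {
  # constant diameter 5 mm: a_norm = pi * (5 / 16)^2
  an <- rep(pi * (5 / 16)^2, 100)
  r <- pupillary_response(an, c(0, 49), c(50, 99))
  expect_equal(r$response_mm, 0)
  expect_equal(r$baseline_mean_mm, 5)
  # 5.7 mm baseline, 6.6 mm stimulation
  an2 <- c(rep(pi * (5.7 / 16)^2, 60), rep(pi * (6.6 / 16)^2, 40))
  r2 <- pupillary_response(an2, c(0, 59), c(60, 99))
  expect_equal(r2$response_mm, 0.9)
  # averaging on a_norm first differs from averaging diameters (Jensen)
  an3 <- c(rep(0.01, 50), rep(0.04, 50))
  r3 <- pupillary_response(an3, c(0, 99), c(0, 99))
  expect_equal(r3$baseline_mean_mm, diameter_mm(mean(an3)))
  expect_false(isTRUE(all.equal(r3$baseline_mean_mm, mean(diameter_mm(an3)))))
  # all-missing window raises an insufficient-data error naming the window
  an4 <- an2; an4[61:100] <- NA
  expect_error(pupillary_response(an4, c(0, 59), c(60, 99)), "stimulation",
               class = "pupilkit_insufficient_data_error")
  expect_error(pupillary_response(an2, c(0, 120), c(60, 99)),
               class = "pupilkit_contract_error")
})
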