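test_that("completion-by-sex table reproduces the published phi_c2 and p", {
  tab <- matrix(c(993, 335, 267, 52), nrow = 2, byrow = TRUE)
  res <- chi_square_phi2(tab)
  expect_equal(round(res$phi_c2, 3), 0.007)
  expect_equal(round(res$p_value, 3), 0.001)
  expect_equal(res$n, 1647)
  expect_equal(res$df, 1)
})

test_that("independent rows give zero association", {
  res <- chi_square_phi2(matrix(c(50, 50, 50, 50), 2, 2))
  expect_equal(res$chi2, 0)
  expect_equal(res$phi_c2, 0)
})

test_that("phi_c2 matches a hand-expanded chi-square on a 3x2 table", {
  tab <- matrix(c(10, 0, 0, 10, 5, 5), nrow = 3, byrow = TRUE)
  res <- chi_square_phi2(tab)
  expect_equal(res$chi2, oracle_chi2(tab), tolerance = 1e-12)
  expect_equal(res$phi_c2, oracle_chi2(tab) / (30 * 1), tolerance = 1e-12)
  expect_equal(res$df, 2)
})

test_that("phi_c2 stays in [0,1] and equals chi2/n for 2x2 tables", {
  set.seed(11)
  for (i in 1:200) {
    nr <- sample(2:4, 1)
    nc <- sample(2:4, 1)
    tab <- random_table(nr, nc)
    res <- chi_square_phi2(tab)
    expect_gte(res$phi_c2, 0)
    expect_lte(res$phi_c2, 1)
    expect_equal(res$chi2, oracle_chi2(tab), tolerance = 1e-9)
    if (nr == 2 && nc == 2) {
      expect_equal(res$phi_c2, res$chi2 / sum(tab), tolerance = 1e-12)
    }
  }
})

test_that("degenerate tables are rejected", {
  expect_error(chi_square_phi2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "all-zero")
  expect_error(chi_square_phi2(matrix(1:3, 3, 1)), "at least 2")
})

test_that("representativeness is zero when enrollment mirrors eligibility", {
  res <- representativeness_phi2(c(200, 200), c(0.5, 0.5), 8000)
  expect_equal(res$phi_c2, 0, tolerance = 1e-12)
})

test_that("representativeness equals the directly built 2x2 table", {
  enrolled <- c(30, 0)
  res <- representativeness_phi2(enrolled, c(0.5, 0.5), 200)
  manual <- chi_square_phi2(rbind(c(30, 0), c(100 - 30, 100)))
  expect_equal(res$phi_c2, manual$phi_c2, tolerance = 1e-12)
  expect_equal(attr(res, "convention"), "participant_vs_nonparticipant")
})

test_that("representativeness at the published sex margins is convention-dependent", {
  # 1,561 women / 391 men enrolled; 54.1% of 32,878 eligible are women.
  res <- representativeness_phi2(c(1561, 391), c(0.541, 0.459), 32878)
  expect_gt(res$phi_c2, 0)
  expect_lt(res$phi_c2, 1)
  # The value is reported as computed under the documented construction;
  # it is not forced toward any externally published figure.
  expect_equal(res$n, 32878)
})

test_that("representativeness rejects impossible enrollment", {
  expect_error(representativeness_phi2(c(10, 5), c(1, 0), 100), "zero eligible")
  expect_error(representativeness_phi2(c(80, 80), c(0.5, 0.5), 100),
               "exceeds")
})

test_that("no change between timepoints gives zero time effect", {
  x <- c(3, 7, 1, 9, 4)
  res <- rm_anova_two_timepoints(x, x)
  expect_equal(res$ss_time, 0)
  expect_equal(res$eta2_time, 0)
  expect_false(res$degenerate)
})

test_that("ungrouped eta2_time equals t^2/(t^2+n-1) from a paired t-test", {
  set.seed(5)
  base <- rnorm(10, 220, 30)
  fup <- base - rnorm(10, 12, 6)
  res <- rm_anova_two_timepoints(base, fup)
  tt <- t.test(fup, base, paired = TRUE)
  t2 <- unname(tt$statistic)^2
  expect_equal(res$f_time, t2, tolerance = 1e-10)
  expect_equal(res$eta2_time, t2 / (t2 + 9), tolerance = 1e-10)
  expect_equal(res$p_time, tt$p.value, tolerance = 1e-10)
})

test_that("constant within-group change with a group shift saturates the interaction", {
  base <- c(100, 110, 120, 200, 210, 220)
  d <- c(rep(-5, 3), rep(-15, 3))
  res <- rm_anova_two_timepoints(base, base + d, rep(c("a", "b"), each = 3))
  expect_equal(res$eta2_interaction, 1)
  expect_equal(res$ss_within_error, 0)
})

test_that("mixed decomposition matches the brute-force cell-means oracle", {
  set.seed(33)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    sizes <- sample(2:5, k, replace = TRUE)
    n <- sum(sizes)
    if (n < 3) next
    g <- rep(letters[seq_len(k)], sizes)
    base <- rnorm(n, 200, 25)
    fup <- base + rnorm(n, -10, 8) + as.integer(factor(g)) * rnorm(1, 0, 4)
    res <- rm_anova_two_timepoints(base, fup, if (k > 1) g else NULL)
    orc <- oracle_mixed_anova(base, fup, if (k > 1) g else NULL)
    expect_equal(res$ss_time, orc$ss_time, tolerance = 1e-9)
    expect_equal(res$ss_interaction, orc$ss_interaction, tolerance = 1e-9)
    expect_equal(res$ss_within_error, orc$ss_within_error, tolerance = 1e-9)
  }
})

test_that("interaction F equals the unweighted-means ANOVA on change scores", {
  set.seed(77)
  for (i in 1:20) {
    sizes <- sample(3:12, 3, replace = TRUE)
    g <- rep(c("x", "y", "z"), sizes)
    base <- rnorm(sum(sizes), 180, 20)
    fup <- base + rnorm(sum(sizes), -8, 5)
    res <- rm_anova_two_timepoints(base, fup, g)
    expect_equal(res$f_interaction, oracle_diff_score_f(fup - base, g),
                 tolerance = 1e-9)
  }
})

test_that("eta2 values are bounded in [0,1] over random paired data", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    base <- rnorm(n)
    fup <- base + rnorm(n, sample(c(-1, 0, 2), 1))
    g <- if (n >= 6) sample(c("a", "b"), n, replace = TRUE) else NULL
    if (!is.null(g) && min(table(g)) < 2) g <- NULL
    res <- rm_anova_two_timepoints(base, fup, g)
    expect_true(res$eta2_time >= 0 && res$eta2_time <= 1)
    expect_true(res$eta2_interaction >= 0 && res$eta2_interaction <= 1)
  }
})

test_that("degenerate and undersized inputs are handled", {
  expect_error(rm_anova_two_timepoints(c(1, 2), c(1, 2)), "At least 3")
  expect_error(
    rm_anova_two_timepoints(1:6, 2:7, c("a", "a", "a", "a", "a", "b")),
    "singleton"
  )
  res <- rm_anova_two_timepoints(rep(5, 4), rep(5, 4))
  expect_true(res$degenerate)
  expect_equal(res$eta2_time, 0)
})

test_that("missing pairs are excluded listwise per analysis", {
  base <- c(1, 2, NA, 4, 5)
  fup <- c(2, NA, 3, 5, 7)
  res <- rm_anova_two_timepoints(base, fup)
  expect_equal(res$n_subjects, 3)
})

test_that("summaries switch style on skewness", {
  s <- summarize_measure(c(1, 2, 3, 4, 5))
  expect_equal(s$style, "mean_sd")
  expect_equal(s$central, 3)

  set.seed(8)
  x <- exp(rnorm(500, 0, 1))
  s2 <- summarize_measure(x)
  expect_equal(s2$style, "median_iqr")
  expect_equal(s2$skewness, oracle_skewness(x), tolerance = 1e-10)
  expect_equal(s2$central, unname(quantile(x, 0.5, type = 7)))
  expect_lte(s2$spread_low, s2$central)
  expect_gte(s2$spread_high, s2$central)

  s3 <- summarize_measure(c(5, 5, 5))
  expect_equal(s3$style, "mean_sd")
  expect_equal(s3$sd, 0)

  expect_error(summarize_measure(c(1, NA)), "At least 2")
})

test_that("summaries are invariant to input order", {
  set.seed(13)
  x <- rgamma(101, 1.2, 1)
  a <- summarize_measure(x)
  b <- summarize_measure(sample(x))
  expect_equal(a[c("central", "spread_low", "spread_high", "style", "n")],
               b[c("central", "spread_low", "spread_high", "style", "n")])
})
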