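test_that("chi-square of proportions reproduces the printed worked values", {
  # uncorrected
  expect_equal(chi2_proportions(31, 73, 5, 49)$statistic, 14.67,
               tolerance = 5e-4)
  expect_equal(chi2_proportions(0, 28, 10, 32)$statistic, 10.5,
               tolerance = 5e-4)
  expect_equal(chi2_proportions(0, 28, 6, 32)$statistic, 5.8333,
               tolerance = 5e-5)
  expect_equal(chi2_proportions(41, 54, 33, 54)$statistic, 2.7472,
               tolerance = 5e-5)
  # the one printed value that needs Yates' correction
  expect_equal(chi2_proportions(17, 54, 23, 91, correction = TRUE)$statistic,
               0.38, tolerance = 2e-3)
  expect_equal(chi2_proportions(10, 50, 10, 50)$statistic, 0)
  expect_error(chi2_proportions(0, 10, 0, 12), "degenerate")
})

test_that("chi-square agrees with the vetted implementation and z^2 identity", {
  set.seed(5)
  for (i in 1:10) {
    n1 <- sample(20:100, 1)
    n2 <- sample(20:100, 1)
    k1 <- sample.int(n1 - 1, 1)
    k2 <- sample.int(n2 - 1, 1)
    for (corr in c(FALSE, TRUE)) {
      ours <- chi2_proportions(k1, n1, k2, n2, correction = corr)
      ref <- suppressWarnings(stats::chisq.test(
        matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE),
        correct = corr))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
    # z-statistic identity (uncorrected)
    p1 <- k1 / n1
    p2 <- k2 / n2
    pp <- (k1 + k2) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(chi2_proportions(k1, n1, k2, n2)$statistic, z^2,
                 tolerance = 1e-10)
  }
})

test_that("Kuiper test separates shifted circular samples and not identical ones", {
  set.seed(6)
  a <- rvonmises(200, 0, 2)
  same <- kuiper_two_sample(a, a, n_perm = 199, seed = 1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_gt(same$p, 0.9)
  b <- rvonmises(200, pi, 2)
  diffp <- kuiper_two_sample(a, b, n_perm = 999, seed = 2)
  expect_lt(diffp$p, 0.01)
  expect_error(kuiper_two_sample(a[1:3], b), "at least 5")
})

test_that("the Kuiper statistic is rotation invariant", {
  set.seed(7)
  a <- runif(40, 0, 2 * pi)
  b <- rvonmises(35, 1, 1)
  v0 <- kuiper_two_sample(a, b, n_perm = 99, seed = 1)$statistic
  for (rot in c(0.7, 2.1, 4.4)) {
    vr <- kuiper_two_sample((a + rot) %% (2 * pi), (b + rot) %% (2 * pi),
                            n_perm = 99, seed = 1)$statistic
    expect_equal(vr, v0, tolerance = 1e-12)
  }
})

test_that("Kuiper permutation p-values are uniform under the null", {
  set.seed(8)
  pv <- replicate(200, {
    x <- runif(20, 0, 2 * pi)
    y <- runif(20, 0, 2 * pi)
    kuiper_two_sample(x, y, n_perm = 99)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("the IQR outlier rule matches its interpolated-quartile oracle", {
  expect_equal(remove_outliers_iqr(c(1, 2, 3, 4, 5))$kept, c(1, 2, 3, 4, 5))
  out <- remove_outliers_iqr(c(1, 2, 3, 4, 100))
  expect_equal(out$kept, c(1, 2, 3, 4)) # Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_equal(out$removed, 5L)
  expect_equal(remove_outliers_iqr(rep(7, 6))$kept, rep(7, 6))
  expect_message(short <- remove_outliers_iqr(c(1, 100)), "fewer than 4")
  expect_equal(short$kept, c(1, 100))
  # single-pass semantics: every kept value lies inside the original
  # fences, so re-filtering with those fences removes nothing
  set.seed(9)
  for (i in 1:10) {
    v <- rt(30, df = 2)
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    k1 <- remove_outliers_iqr(v)$kept
    expect_true(all(k1 >= fence[1] & k1 <= fence[2]))
    expect_length(setdiff(v[v >= fence[1] & v <= fence[2]], k1), 0)
  }
})

test_that("nonparametric wrappers reproduce hand-computed statistics", {
  # signed rank: differences 5, 9, 13 all positive -> V = 1 + 2 + 3 = 6
  sr <- wilcoxon_signed_rank(c(10, 14, 20), c(5, 5, 7))
  expect_equal(sr$statistic, 6)
  # Friedman via its rank formula on a worked matrix
  m <- matrix(c(1, 2, 3,
                2, 1, 3,
                1, 3, 2,
                1, 2, 3), 4, 3, byrow = TRUE)
  fr <- friedman_rm(m, posthoc_ref = NULL)
  rank_sums <- colSums(m)
  chi_hand <- 12 / (4 * 3 * 4) * sum(rank_sums^2) - 3 * 4 * 4
  expect_equal(fr$statistic, chi_hand)
  expect_equal(fr$df, 2)
  # Kruskal-Wallis on ranks 1..6 split into two groups of 3
  kw <- kruskal(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  h_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(kw$statistic, h_hand)
  # Bonferroni post hocs are the raw p times the number of comparisons
  set.seed(10)
  mm <- matrix(rnorm(40), 10, 4)
  fr2 <- friedman_rm(mm, posthoc_ref = 1)
  expect_equal(fr2$posthoc$p_bonferroni,
               pmin(1, fr2$posthoc$p_raw * 3))
  # tidy() returns the broom-style one-row frame
  td <- tidy(sr)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$statistic, 6)
})
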