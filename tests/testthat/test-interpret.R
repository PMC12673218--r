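test_that("the correlation time course matches hand Pearson computations", {
  # 4 channels, single time point: |eeg| = 1:4 against proportional and
  # reversed features
  e <- matrix(c(1, -2, 3, -4), 4, 1)
  expect_equal(interpretability_timecourse(e, matrix(c(2, 4, 6, 8), 4, 1)), 1)
  expect_equal(interpretability_timecourse(e, matrix(c(4, 3, 2, 1), 4, 1)), -1)
  # self-similarity gives r = 1 at every defined sample
  em <- withr::with_seed(1, matrix(rnorm(8 * 10), 8, 10))
  r <- interpretability_timecourse(em, abs(em))
  expect_equal(r, rep(1, 10))
})

test_that("constant vectors yield undefined correlations, not zeros", {
  e <- matrix(1, 4, 3)           # constant |eeg| at every sample
  f <- matrix(runif(12), 4, 3)
  expect_true(all(is.na(interpretability_timecourse(e, f))))
  expect_error(interpretability_timecourse(matrix(1, 2, 3), matrix(1, 2, 3)),
               "3 channels")
  expect_error(interpretability_timecourse(matrix(1, 4, 3),
                                           matrix(-1, 4, 3)), "nonnegative")
})

test_that("random features decorrelate from the EEG on average", {
  em <- withr::with_seed(2, matrix(rnorm(16 * 200), 16, 200))
  f <- withr::with_seed(3, matrix(runif(16 * 200), 16, 200))
  r <- interpretability_timecourse(em, f)
  expect_lt(abs(mean(r, na.rm = TRUE)), 3 / sqrt(16 * 200 / 16))
})

test_that("signed-rank p-values match exhaustive enumeration for n <= 10", {
  set.seed(31)
  for (n in c(5, 8, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 2)
      d <- d[d != 0]
      if (length(d) < 2) next
      w <- eeginterp:::wilcoxon_signed_rank(d)
      expect_equal(w$p, enumerate_signed_rank_p(d), tolerance = 1e-10,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
  # all-positive n = 8: exact two-sided p = 2/2^8
  w <- eeginterp:::wilcoxon_signed_rank(1:8 / 10)
  expect_equal(w$p, 2 / 2^8)
})

test_that("group significance applies BH correctly", {
  set.seed(12)
  tc <- cbind(matrix(rnorm(8 * 10, 0.8, 0.1), 8, 10),
              matrix(rnorm(8 * 20, 0, 1), 8, 20))
  sig <- group_significance(tc, alpha = 0.05)
  # BH mask is a subset of the raw p < alpha mask
  expect_true(all(which(sig$group_mask) %in% which(sig$p_raw < 0.05)))
  # sorted adjusted p-values are monotone in the raw-p order
  ord <- order(sig$p_raw)
  expect_true(all(diff(sig$p_adjusted[ord]) > -1e-12))
  # all-zero time courses give an empty mask
  sig0 <- group_significance(matrix(0, 6, 5), 0.05)
  expect_true(all(sig0$p_raw == 1))
  expect_false(any(sig0$group_mask))
})

test_that("maximum score and latency follow the stated tie/NA rules", {
  expect_equal(max_score_and_latency(c(0.1, 0.9, 0.4), c(0, 0.1, 0.2)),
               list(max_score = 0.9, max_latency = 0.1))
  expect_equal(max_score_and_latency(c(0.5, 0.5), c(0.1, 0.2))$max_latency,
               0.1)
  expect_equal(max_score_and_latency(c(NA, 0.3, 0.7, NA), 1:4),
               list(max_score = 0.7, max_latency = 3))
  expect_error(max_score_and_latency(c(NA, NA), 1:2), "undefined")
})

test_that("paired comparisons behave like a signed-rank test", {
  a <- c(0.61, 0.55, 0.72, 0.44, 0.58, 0.63, 0.51)
  b <- a + 0.1
  cmp <- compare_paired(a, b)
  expect_equal(cmp$p_value, 2 / 2^7)
  expect_lt(cmp$z_statistic, 0)
  swapped <- compare_paired(b, a)
  expect_equal(swapped$z_statistic, -cmp$z_statistic)
  expect_equal(swapped$p_value, cmp$p_value)
  same <- compare_paired(a, a)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_paired(1:3, 4:6), "length >= 5")
})

test_that("score calibration: |EEG| features give max score 1, noise gives none", {
  P <- 8; C <- 16; S <- 40
  em <- withr::with_seed(5, array(rnorm(C * S * P), c(C, S, P)))
  res <- interpretability_score(em, abs(em), times = seq_len(S) / 100)
  expect_equal(unname(res$max_scores), rep(1, P))
  expect_true(all(res$group_mask))
})
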