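test_that("cross-entropy matches closed forms", {
  expect_equal(cross_entropy(diag(3), diag(3)), 0)
  expect_equal(cross_entropy(matrix(c(1, 0, 0), 1), matrix(1 / 3, 1, 3)),
               log(3))
  expect_equal(cross_entropy(matrix(c(1, 0, 0), 1),
                             matrix(c(0.7, 0.2, 0.1), 1)),
               -log(0.7))
  # batch average
  expect_equal(cross_entropy(rbind(c(1, 0), c(0, 1)),
                             rbind(c(0.5, 0.5), c(0.25, 0.75))),
               mean(-log(c(0.5, 0.75))))
})

test_that("zero probability at the true class clamps with a warning", {
  expect_warning(
    v <- cross_entropy(matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
    "clamping")
  expect_true(is.finite(v) && v > 0)
  expect_error(cross_entropy(matrix(c(1, 0), 1), matrix(c(0.4, 0.4), 1)),
               "sum to 1")
})

test_that("categorical accuracy is the exact match fraction", {
  expect_equal(categorical_accuracy(rep("a", 10), rep("a", 10)), 1)
  expect_equal(categorical_accuracy(c("a", "a", "b", "b"),
                                    c("a", "b", "b", "a")), 0.5)
  expect_error(categorical_accuracy(character(), character()), "nonempty")
})

test_that("self-permuted balanced labels score near 1/3", {
  labs <- rep(c("a", "b", "c"), each = 2000)
  perm <- withr::with_seed(4, sample(labs))
  acc <- categorical_accuracy(perm, labs)
  # 99.9% binomial interval around 1/3 for n = 6000
  expect_lt(abs(acc - 1 / 3), 3.29 * sqrt(1 / 3 * 2 / 3 / 6000))
})
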