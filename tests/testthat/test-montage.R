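test_that("fibonacci montage yields unique labels on the unit upper hemisphere", {
  m <- fibonacci_montage(32)
  expect_length(m$channel_labels, 32)
  expect_false(anyDuplicated(m$channel_labels) > 0)
  expect_true(all(abs(sqrt(rowSums(m$positions^2)) - 1) < 1e-9))
  expect_true(all(m$positions[, 3] > 0))
})

test_that("montage constructor validates geometry", {
  expect_error(montage(c("a", "a"), diag(2)[, c(1, 2, 2)]), "unique")
  expect_error(montage(c("a", "b"), matrix(c(1, 0, 0, 2, 0, 0), 2,
                                           byrow = TRUE)), "unit sphere")
  expect_error(fibonacci_montage(4), ">= 8")
})

test_that("montage CSV round trip preserves labels and positions", {
  m <- fibonacci_montage(16)
  f <- tempfile(fileext = ".csv")
  write_montage_csv(m, f)
  m2 <- read_montage_csv(f)
  expect_identical(m2$channel_labels, m$channel_labels)
  expect_true(max(abs(m2$positions - m$positions)) < 1e-12)
  unlink(f)
})
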