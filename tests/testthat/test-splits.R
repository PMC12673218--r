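test_that("26 participants split 81/10/9 into sizes 21/3/2 covering everyone", {
  pp <- sprintf("P%02d", 1:26)
  plan <- make_participant_splits(pp, 5, seed = 3)
  for (fo in plan$folds) {
    expect_length(fo$train, 21)
    expect_length(fo$val, 3)
    expect_length(fo$test, 2)
    expect_setequal(c(fo$train, fo$val, fo$test), pp)
  }
})

test_that("sets are pairwise disjoint and test sets rotate across folds", {
  for (seed in 1:5) {
    plan <- make_participant_splits(sprintf("S%d", 1:20), 5, seed = seed)
    for (fo in plan$folds) {
      expect_length(intersect(fo$train, fo$test), 0)
      expect_length(intersect(fo$train, fo$val), 0)
      expect_length(intersect(fo$val, fo$test), 0)
    }
    tests <- lapply(plan$folds, `[[`, "test")
    expect_gt(length(unique(tests)), 1)
  }
})

test_that("split plans are seed-deterministic", {
  a <- make_participant_splits(sprintf("S%d", 1:20), 5, seed = 9)
  b <- make_participant_splits(sprintf("S%d", 1:20), 5, seed = 9)
  expect_identical(a$folds, b$folds)
})

test_that("degenerate inputs are rejected", {
  expect_error(make_participant_splits(c("a", "b")), "at least 3")
  expect_error(make_participant_splits(letters[1:10],
                                       fractions = c(0.5, 0.2, 0.2)),
               "summing to 1")
})
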