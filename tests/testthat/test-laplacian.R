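test_that("the surface Laplacian annihilates spatially constant maps", {
  mont <- fibonacci_montage(32)
  x <- matrix(5, 32, 4)
  out <- surface_laplacian(x, mont)
  expect_lt(max(abs(out)), 1e-6 * 5)
})

test_that("the transform is linear", {
  mont <- fibonacci_montage(24)
  set.seed(8)
  x <- matrix(rnorm(24 * 3), 24, 3)
  y <- matrix(rnorm(24 * 3), 24, 3)
  lhs <- surface_laplacian(2 * x - 3 * y, mont)
  rhs <- 2 * surface_laplacian(x, mont) - 3 * surface_laplacian(y, mont)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("the transform commutes with channel relabeling", {
  mont <- fibonacci_montage(20)
  set.seed(9)
  x <- rnorm(20)
  perm <- sample(20)
  mont_p <- montage(mont$channel_labels[perm], mont$positions[perm, ])
  out <- surface_laplacian(x, mont)
  out_p <- surface_laplacian(x[perm], mont_p)
  expect_equal(out_p, out[perm], tolerance = 1e-9)
})

test_that("midline-symmetric inputs stay symmetric", {
  # build an explicitly mirror-symmetric montage about x = 0
  phi <- seq(0.2, 1.2, length.out = 5)
  th <- seq(0.3, 2.8, length.out = 4)
  grid <- expand.grid(phi = phi, th = th)
  pos <- cbind(sin(grid$phi) * cos(grid$th), sin(grid$phi) * sin(grid$th),
               cos(grid$phi))
  pos_m <- pos; pos_m[, 1] <- -pos_m[, 1]
  keep <- abs(pos[, 1]) > 1e-6
  all_pos <- rbind(pos[keep, ], pos_m[keep, ])
  mont <- montage(sprintf("e%02d", seq_len(nrow(all_pos))), all_pos)
  n <- sum(keep)
  v_half <- rnorm(n)
  v <- c(v_half, v_half)  # symmetric input on mirrored pairs
  out <- surface_laplacian(v, mont)
  expect_equal(out[seq_len(n)], out[n + seq_len(n)], tolerance = 1e-9)
})

test_that("duplicate electrodes and bad parameters are rejected", {
  mont <- fibonacci_montage(16)
  dup <- montage(c(mont$channel_labels, "dup"),
                 rbind(mont$positions, mont$positions[1, ]))
  expect_error(surface_laplacian(rnorm(17), dup), "duplicate")
  expect_error(laplacian_params(lambda2 = 0), "lambda2")
  expect_error(laplacian_params(stiffness = 1.5), "stiffness")
})
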