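test_that("trial bookkeeping matches the design", {
  cfg <- sim_config_3class(n_participants = 4, trials_per_class = 50,
                           seed = 5)
  ep <- simulate_dataset(cfg)
  expect_equal(dim(ep$data), c(600, 32, 192))
  expect_equal(length(ep$times), 192)
  expect_equal(ep$sampling_rate, 256)
  # every (participant, class) cell is exactly balanced
  tab <- table(ep$participants, ep$labels)
  expect_true(all(tab == 50))
})

test_that("the noise-free limit reproduces the class template exactly", {
  cfg <- sim_config_3class(n_participants = 2, trials_per_class = 4,
                           seed = 2, noise_sd = 0, latency_jitter_sd = 0,
                           participant_amplitude_sd = 0,
                           participant_topography_sd = 0)
  ep <- simulate_dataset(cfg)
  for (cl in levels(ep$labels)) {
    idx <- which(ep$labels == cl & ep$participants == "P01")
    tmpl <- ep$data[idx[1], , ]
    for (i in idx[-1]) expect_equal(ep$data[i, , ], tmpl)
    # the same class template holds for the other participant too
    idx2 <- which(ep$labels == cl & ep$participants == "P02")
    expect_equal(ep$data[idx2[1], , ], tmpl)
  }
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- simulate_dataset(tiny_sim(seed = 7))
  b <- simulate_dataset(tiny_sim(seed = 7))
  c <- simulate_dataset(tiny_sim(seed = 8))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("every sample is common-average referenced", {
  ep <- simulate_dataset(tiny_sim())
  ch_means <- apply(ep$data, c(1, 3), mean)
  expect_lt(max(abs(ch_means)), 1e-9 * max(abs(ep$data)))
})

test_that("grand averages converge to the noiseless template as 1/sqrt(n)", {
  base <- list(n_participants = 1, trials_per_class = 1, seed = 21,
               latency_jitter_sd = 0, participant_amplitude_sd = 0,
               participant_topography_sd = 0)
  clean <- simulate_dataset(do.call(sim_config_3class,
                                    c(base, noise_sd = 0)))
  tmpl <- clean$data[which(clean$labels == "A"), , ]
  rms_at <- function(n) {
    cfg <- do.call(sim_config_3class,
                   c(list(n_participants = 1, trials_per_class = n,
                          seed = 22, latency_jitter_sd = 0,
                          participant_amplitude_sd = 0,
                          participant_topography_sd = 0), noise_sd = 6))
    ep <- simulate_dataset(cfg)
    ga <- apply(ep$data[ep$labels == "A", , , drop = FALSE], c(2, 3), mean)
    sqrt(mean((ga - tmpl)^2))
  }
  r16 <- rms_at(16)
  r64 <- rms_at(64)
  # expected ratio 1/2; allow 3x sampling slack
  expect_lt(r64, r16)
  expect_lt(r64 / r16, 0.5 * 3)
})

test_that("ground-truth masks unroll the component definition", {
  mont <- fibonacci_montage(32)
  pat <- numeric(32)
  pat[c(2, 5, 9, 12, 20, 31)] <- c(1, 0.9, 0.8, 0.8, 0.7, 0.6)
  cfg <- sim_config(2, 4, c("sig", "none"),
                    list(component_spec(0.15, 0.05, 5, pat, "sig")),
                    mont = mont, seed = 1)
  m <- ground_truth_mask(cfg, "sig")
  times <- (seq_len(192) - 1) / 256
  on_ch <- which(rowSums(m) > 0)
  expect_identical(on_ch, c(2L, 5L, 9L, 12L, 20L, 31L))
  on_t <- which(colSums(m) > 0)
  expect_true(all(abs(times[on_t] - 0.15) <= 0.05 + 1e-9))
  expect_true(all(abs(times[-on_t] - 0.15) > 0.05))
  # stimulation-free class has an all-zero mask
  expect_true(all(ground_truth_mask(cfg, "none") == 0))
  expect_error(ground_truth_mask(cfg, "nope"), "unknown class")
})

test_that("overlapping components union their masks", {
  mont <- fibonacci_montage(32)
  p1 <- numeric(32); p1[1:4] <- 1
  p2 <- numeric(32); p2[3:8] <- 1
  one <- function(comps) {
    sim_config(2, 2, c("s", "n"), comps, mont = mont, seed = 1)
  }
  m1 <- ground_truth_mask(one(list(component_spec(0.15, 0.03, 5, p1, "s"))), "s")
  m2 <- ground_truth_mask(one(list(component_spec(0.20, 0.03, 5, p2, "s"))), "s")
  m12 <- ground_truth_mask(one(list(component_spec(0.15, 0.03, 5, p1, "s"),
                                    component_spec(0.20, 0.03, 5, p2, "s"))), "s")
  expect_identical(m12, pmax(m1, m2))
})

test_that("invalid configurations are rejected with the component name", {
  mont <- fibonacci_montage(32)
  pat <- c(1, numeric(31))
  expect_error(
    sim_config(2, 2, c("a", "b"),
               list(component_spec(0.9, 0.03, 5, pat, "a", name = "late-bump")),
               mont = mont),
    "late-bump")
  expect_error(component_spec(0.1, 0.03, 5, numeric(32), "a"), "nonzero")
  expect_error(sim_config(0, 2, c("a", "b"), list(), mont = mont), "count")
})
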