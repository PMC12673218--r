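test_that("the time-resolved logistic baseline localizes a planted component", {
  mont <- fibonacci_montage(16)
  pat <- spatial_pattern_around(mont, c(0, -0.8, 0.6), n_channels = 5)
  cfg <- sim_config(4, 25, c("sig", "none"),
                    list(component_spec(0.15, 0.02, 6, pat, "sig")),
                    mont = mont, sampling_rate = 128,
                    epoch_window = c(0, 0.5), noise_sd = 3,
                    latency_jitter_sd = 0, seed = 13)
  ep <- simulate_dataset(cfg)
  train <- subset_participants(ep, c("P01", "P02", "P03"))
  test <- subset_participants(ep, "P04")
  res <- pointwise_logreg_baseline(train, test)
  # reported maximum is the max of the returned curve
  expect_equal(res$max_accuracy, max(res$accuracy_timecourse))
  # the accuracy peak sits within 2 samples of the planted latency
  dt <- 1 / 128
  peak_t <- res$times[which.max(res$accuracy_timecourse)]
  expect_lte(abs(peak_t - 0.15), 2 * dt)
  # far from the component (no signal by construction) accuracy is ~ chance
  early <- res$accuracy_timecourse[res$times < 0.05]
  n_early_trials <- length(test$labels) * length(early)
  expect_lt(abs(mean(early) - 0.5), 3 * sqrt(0.25 / n_early_trials) + 0.05)
})
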