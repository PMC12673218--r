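test_that("forward passes return proper probability vectors", {
  for (mk in list(tiny_eegnet_spec, tiny_resnet_spec)) {
    dec <- build_decoder(mk(), 6, 32, 3, seed = 2)
    X0 <- array(0, c(6, 32, 4))
    p <- eeginterp:::decoder_forward(dec, X0)$probs
    expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
    expect_true(all(p >= 0))
    Xr <- array(rnorm(6 * 32 * 4), c(6, 32, 4))
    p2 <- eeginterp:::decoder_forward(dec, Xr)$probs
    expect_equal(colSums(p2), rep(1, 4), tolerance = 1e-6)
  }
})

test_that("the EEGNet-style family names exactly three convolution layers", {
  expect_identical(architecture_spec("eegnet_style")$named_layers,
                   c("conv1", "conv2", "conv3"))
  pre <- layer_presets(architecture_spec("residual_small"))
  expect_named(pre, c("early", "intermediate", "late"))
})

test_that("parameter counts match layer-by-layer hand arithmetic", {
  # eegnet: C=6, T=32, 3 classes; k1=5,F1=2,D=2 (F2=F3=4), k3=7, pools 2/2
  # W1 5*2 + b1 2 + W2 6*4 + b2 4 + W3d 7*4 + W3p 4*4 + b3 4
  #   + W4 (8*4)*3 + b4 3 = 187
  expect_equal(n_parameters(build_decoder(tiny_eegnet_spec(), 6, 32, 3)), 187)
  # resnet: k=5, F=4, 2 blocks (no widening below 3 blocks)
  # W0 5*6*4 + b0 4 + 2*(5*4*4 + 4 + 5*4*4 + 4) + Wd 4*3 + bd 3 = 475
  expect_equal(n_parameters(build_decoder(tiny_resnet_spec(), 6, 32, 3)), 475)
})

test_that("kernels longer than the input are rejected", {
  spec <- architecture_spec("eegnet_style", temporal_kernel_length = 40)
  expect_error(build_decoder(spec, 6, 32, 3), "longer than")
  spec2 <- architecture_spec("eegnet_style", temporal_kernel_length = 5,
                             separable_kernel_length = 64,
                             pool_sizes = c(2, 2))
  expect_error(build_decoder(spec2, 6, 32, 3), "longer than")
})

test_that("training separates a noiseless two-class problem", {
  cfg <- sim_config_prepost(n_participants = 3, trials_per_class = 12,
                            seed = 6, noise_sd = 0, latency_jitter_sd = 0,
                            participant_amplitude_sd = 0,
                            participant_topography_sd = 0)
  ep <- simulate_dataset(cfg)
  dec <- build_decoder(architecture_spec("eegnet_style"), 32, 192, 2,
                       levels(ep$labels), seed = 1)
  tc <- train_config(optimizer = "sgd_momentum", learning_rate = 0.01,
                     max_epochs = 10, seed = 1)
  tr <- train_decoder(dec, subset_participants(ep, c("P01", "P02")),
                      subset_participants(ep, "P03"), tc)
  expect_equal(max(tr$history$train_acc), 1)
  expect_lt(min(tr$history$train_loss), tr$history$train_loss[1])
})

test_that("early stopping fires after `patience` epochs without improvement", {
  ep <- simulate_dataset(tiny_sim(n_participants = 3, trials_per_class = 4))
  dec <- build_decoder(tiny_eegnet_spec(), 32, 192, 3, levels(ep$labels))
  # a vanishing learning rate freezes the weights, so the validation loss
  # never decreases after the first epoch
  tc <- train_config(learning_rate = 1e-30, max_epochs = 50,
                     early_stop_patience = 3, seed = 1)
  tr <- train_decoder(dec, subset_participants(ep, c("P01", "P02")),
                      subset_participants(ep, "P03"), tc)
  expect_equal(nrow(tr$history), 4)  # 1 best epoch + 3 stalls
  expect_equal(tr$best_epoch, 1)
})

test_that("training is reproducible for identical data, config, and seed", {
  ep <- simulate_dataset(tiny_sim(n_participants = 3))
  tc <- train_config(learning_rate = 0.01, max_epochs = 3, seed = 5)
  runs <- lapply(1:2, function(i) {
    dec <- build_decoder(tiny_eegnet_spec(), 32, 192, 3, levels(ep$labels),
                         seed = 4)
    train_decoder(dec, subset_participants(ep, c("P01", "P02")),
                  subset_participants(ep, "P03"), tc)
  })
  expect_identical(runs[[1]]$history, runs[[2]]$history)
  expect_identical(runs[[1]]$params, runs[[2]]$params)
})

test_that("leakage guards reject shared participants", {
  ep <- simulate_dataset(tiny_sim(n_participants = 3))
  dec <- build_decoder(tiny_eegnet_spec(), 32, 192, 3, levels(ep$labels))
  expect_error(
    train_decoder(dec, subset_participants(ep, c("P01", "P02")),
                  subset_participants(ep, c("P02", "P03")),
                  train_config(max_epochs = 1)),
    "leakage")
})

test_that("evaluation is internally consistent and guards test leakage", {
  ep <- simulate_dataset(tiny_sim(n_participants = 4, trials_per_class = 9))
  dec <- build_decoder(tiny_eegnet_spec(), 32, 192, 3, levels(ep$labels))
  tr <- train_decoder(dec, subset_participants(ep, c("P01", "P02")),
                      subset_participants(ep, "P03"),
                      train_config(max_epochs = 1, seed = 1))
  ev <- evaluate_decoder(tr, subset_participants(ep, "P04"))
  expect_identical(ev$accuracy, mean(ev$per_trial_correct))
  expect_identical(as.character(ev$per_trial_predictions) ==
                     as.character(ev$labels),
                   ev$per_trial_correct)
  expect_error(evaluate_decoder(tr, subset_participants(ep, "P01")),
               "leakage")
})

test_that("a constant decoder scores 1/n_classes on a balanced test set", {
  ep <- simulate_dataset(tiny_sim(n_participants = 2, trials_per_class = 10))
  dec <- build_decoder(tiny_eegnet_spec(), 32, 192, 3, levels(ep$labels))
  dec$params <- lapply(dec$params, function(p) p * 0)
  dec$params$b4 <- c(5, 0, 0)  # always predicts the first class
  ev <- evaluate_decoder(dec, ep, check_leakage = FALSE)
  expect_equal(ev$accuracy, 1 / 3)
})
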