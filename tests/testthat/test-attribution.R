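test_that("saliency equals central finite differences on small networks", {
  for (mk in list(tiny_eegnet_spec, tiny_resnet_spec)) {
    dec <- build_decoder(mk(), 6, 32, 3, seed = 7)
    expect_lt(n_parameters(dec), 1e4)
    trial <- withr::with_seed(1, matrix(rnorm(6 * 32), 6, 32))
    for (cls in c(1, 3)) {
      m <- saliency_map(dec, trial, cls)
      expect_identical(dim(m$values), dim(trial))
      expect_identical(m$sign_convention, "signed")
      picks <- withr::with_seed(cls, sample(length(trial), 25))
      fd <- fd_saliency(dec, trial, cls, picks)
      expect_gt(sum(fd$smooth), 15)
      scale <- max(abs(m$values))
      expect_lt(max(abs(m$values[picks][fd$smooth] - fd$fd[fd$smooth])) /
                  scale, 1e-3)
    }
  }
})

test_that("the saliency of a linear softmax readout is the class weight map", {
  # an eegnet whose conv path is forced to the identity-like regime:
  # zero conv weights mean the logit depends only on the bias, so the
  # input gradient must vanish
  dec <- build_decoder(tiny_eegnet_spec(), 6, 32, 2, seed = 1)
  dec$params <- lapply(dec$params, function(p) p * 0)
  trial <- matrix(rnorm(6 * 32), 6, 32)
  m <- saliency_map(dec, trial, 1)
  expect_true(all(m$values == 0))
})

test_that("gradcam matches an explicit per-feature-map loop", {
  for (mk in list(tiny_eegnet_spec, tiny_resnet_spec)) {
    dec <- build_decoder(mk(), 6, 32, 3, seed = 9)
    trial <- withr::with_seed(2, matrix(rnorm(6 * 32), 6, 32))
    times <- (seq_len(32) - 1) / 64
    for (layer in dec$spec$named_layers) {
      g <- eeginterp:::attribution_gradients(
        dec, array(trial, c(6, 32, 1)), 2L, layers = layer)
      act <- g$layer_acts[[layer]]
      grad <- g$layer_grads[[layer]]
      geo <- eeginterp:::layer_geometry(dec, layer, times)
      if (geo$kind == "chan_time") {
        # maps are channels x time grids; loop feature maps explicitly
        oracle <- matrix(0, 6, 32)
        for (f in seq_len(dim(act)[2])) {
          w <- mean(grad[, f, , 1])
          oracle <- oracle + w * t(act[, f, , 1])
        }
        oracle <- pmax(oracle, 0)
      } else {
        comb <- numeric(dim(act)[1])
        for (f in seq_len(dim(act)[2])) {
          w <- mean(grad[, f, 1])
          comb <- comb + w * act[, f, 1]
        }
        comb <- pmax(comb, 0)
        row <- approx(geo$times, comb, xout = times, rule = 2)$y
        oracle <- matrix(row, 6, 32, byrow = TRUE)
      }
      m <- gradcam_map(dec, trial, 2, layer, times = times)
      expect_lt(max(abs(m$values - oracle)), 1e-6)
      expect_gte(min(m$values), 0)
    }
  }
})

test_that("a dead layer yields a flagged all-zero gradcam map, not an error", {
  dec <- build_decoder(tiny_eegnet_spec(), 6, 32, 2, seed = 1)
  dec$params$W4 <- dec$params$W4 * 0  # no gradient reaches any conv layer
  m <- gradcam_map(dec, matrix(rnorm(6 * 32), 6, 32), 1, "conv1")
  expect_true(all(m$values == 0))
  expect_true(attr(m, "dead_layer"))
})

test_that("correct-trial selection returns exactly the correct indices", {
  ev <- structure(list(per_trial_correct = c(TRUE, FALSE, TRUE, FALSE)),
                  class = "evaluation_result")
  expect_identical(select_correct_trials(ev), c(1L, 3L))
  ev$per_trial_correct <- rep(TRUE, 4)
  expect_identical(select_correct_trials(ev), 1:4)
  ev$per_trial_correct <- rep(FALSE, 4)
  expect_length(select_correct_trials(ev), 0)
})

make_map <- function(vals, participant, fold = 1, method = "gradcam") {
  attribution_map(vals, method, if (method == "gradcam") "conv1" else "input",
                  "A", if (method == "gradcam") "nonnegative" else "signed",
                  times = seq_len(ncol(vals)), channels = paste0("c", seq_len(nrow(vals))),
                  fold = fold, participant = participant, trial = 1)
}

test_that("aggregation averages trials, then participants, then folds", {
  ones <- matrix(1, 2, 3); zeros <- matrix(0, 2, 3)
  # participant A: one trial of 1.0; participant B: three trials of 0.0
  maps <- c(list(make_map(ones, "A")),
            lapply(1:3, function(i) make_map(zeros, "B")))
  agg <- aggregate_maps(maps)
  expect_equal(agg$aggregate$values, matrix(0.5, 2, 3))  # not pooled 0.25
  expect_identical(agg$participants, c("A", "B"))
  # balanced designs make the hierarchical mean equal the pooled mean
  bal <- c(lapply(1:2, function(i) make_map(ones, "A")),
           lapply(1:2, function(i) make_map(zeros, "B")))
  expect_equal(aggregate_maps(bal)$aggregate$values, matrix(0.5, 2, 3))
  # aggregating identical maps reproduces the map
  same <- lapply(1:4, function(i) make_map(ones * 0.3, "A", fold = (i > 2) + 1))
  expect_equal(aggregate_maps(same)$aggregate$values, ones * 0.3)
})

test_that("saliency maps aggregate on absolute values", {
  pos <- matrix(1, 2, 2); neg <- matrix(-1, 2, 2)
  maps <- list(make_map(pos, "A", method = "saliency"),
               make_map(neg, "A", method = "saliency"))
  agg <- aggregate_maps(maps)
  expect_equal(agg$aggregate$values, matrix(1, 2, 2))
  expect_identical(agg$aggregate$sign_convention, "nonnegative")
})

test_that("batched trial attribution matches the single-trial entry points", {
  ep <- simulate_dataset(tiny_sim(n_participants = 2, trials_per_class = 2))
  dec <- build_decoder(tiny_eegnet_spec()
                       , 32, 192, 3, levels(ep$labels), seed = 3)
  tl <- attribute_trials(dec, ep, trials = 1:4, method = "gradcam",
                         layer = "conv1", batch = 3)
  for (i in 1:4) {
    single <- gradcam_map(dec, ep$data[i, , ], as.character(ep$labels[i]),
                          "conv1", times = ep$times)
    expect_equal(tl[[i]]$values, single$values, tolerance = 1e-12)
  }
  ts <- attribute_trials(dec, ep, trials = 1:2, method = "saliency")
  for (i in 1:2) {
    single <- saliency_map(dec, ep$data[i, , ], as.character(ep$labels[i]),
                           times = ep$times)
    expect_equal(ts[[i]]$values, single$values, tolerance = 1e-12)
  }
})
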