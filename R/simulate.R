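#' Planted evoked component
#'
#' Describes one class-specific evoked component of the synthetic EEG: a
#' Gaussian time bump (centered at `peak_latency`, sd `temporal_width`)
#' multiplied by a fixed spatial pattern over channels. Components stand in
#' for stereotyped ERP deflections (a visual P1, an auditory N100, ...) whose
#' latency and topography the downstream attribution analysis should recover.
#'
#' @param peak_latency peak time in seconds (>= 0) relative to stimulus onset.
#' @param temporal_width Gaussian sd in seconds (> 0, smaller than the epoch).
#' @param amplitude peak amplitude in microvolts.
#' @param spatial_pattern per-channel weights; rescaled to unit maximum
#'   absolute value; at least one entry must be nonzero.
#' @param class_selector character vector of class names carrying this
#'   component.
#' @param name optional identifier used in error messages.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(peak_latency, temporal_width, amplitude,
                           spatial_pattern, class_selector,
                           name = NULL) {
  if (!is_number(peak_latency) || peak_latency < 0) {
    stopf("peak_latency must be a nonnegative number of seconds")
  }
  if (!is_number(temporal_width) || temporal_width <= 0) {
    stopf("temporal_width must be > 0 seconds")
  }
  if (!is_number(amplitude)) stopf("amplitude must be a number (microvolts)")
  spatial_pattern <- as.numeric(spatial_pattern)
  if (all(spatial_pattern == 0)) {
    stopf("spatial_pattern must have at least one nonzero entry")
  }
  spatial_pattern <- spatial_pattern / max(abs(spatial_pattern))
  class_selector <- as.character(class_selector)
  if (!length(class_selector)) stopf("class_selector must name >= 1 class")
  if (is.null(name)) {
    name <- sprintf("%s@%.3fs", paste(class_selector, collapse = "+"),
                    peak_latency)
  }
  structure(list(peak_latency = peak_latency, temporal_width = temporal_width,
                 amplitude = amplitude, spatial_pattern = spatial_pattern,
                 class_selector = class_selector, name = name),
            class = "component_spec")
}

#' Gaussian spatial pattern around a scalp direction
#'
#' Convenience builder for component topographies: weight each electrode by a
#' Gaussian in great-circle distance from a target direction, keeping only
#' the `n_channels` nearest electrodes, then rescale to unit max-abs. With
#' the default falloff the retained channels all carry weight > 0.5, so they
#' coincide with the ground-truth mask channels.
#'
#' @param mont an [montage()].
#' @param target 3-vector direction on the scalp (normalized internally).
#' @param n_channels number of electrodes given nonzero weight.
#' @param falloff Gaussian sd of the weight profile, radians.
#' @return Numeric per-channel weight vector (unit max-abs).
#' @export
spatial_pattern_around <- function(mont, target, n_channels = 6,
                                   falloff = 0.6) {
  stopifnot(inherits(mont, "eeg_montage"))
  target <- target / sqrt(sum(target^2))
  ang <- acos(pmin(1, pmax(-1, as.numeric(mont$positions %*% target))))
  w <- exp(-ang^2 / (2 * falloff^2))
  keep <- order(ang)[seq_len(n_channels)]
  out <- numeric(length(ang))
  wk <- w[keep]
  # map retained weights onto [0.6, 1] so every retained channel clears the
  # ground-truth mask threshold of 0.5 while preserving the spatial gradient
  if (length(wk) > 1 && max(wk) > min(wk)) {
    wk <- 0.6 + 0.4 * (wk - min(wk)) / (max(wk) - min(wk))
  } else {
    wk <- rep(1, length(wk))
  }
  out[keep] <- wk
  out
}

#' Simulation configuration
#'
#' Full description of a synthetic multi-participant epoched-EEG study:
#' design size, sampling, planted components, 1/f^alpha background noise, and
#' the between-trial / between-participant variability hierarchy.
#'
#' @param n_participants number of participants.
#' @param trials_per_class trials per class per participant.
#' @param class_names character vector of class names (>= 2). Classes with no
#'   component are stimulation-free, emulating pre-stimulus epochs.
#' @param components list of [component_spec()]s.
#' @param mont electrode [montage()]; default 32-channel Fibonacci lattice.
#' @param sampling_rate Hz.
#' @param epoch_window `c(start, end)` seconds relative to stimulus onset.
#' @param noise_sd background-noise sd in microvolts (per channel).
#' @param noise_spectral_exponent alpha of the 1/f^alpha amplitude spectrum.
#' @param latency_jitter_sd per-trial latency jitter sd, seconds.
#' @param participant_amplitude_sd sd of the per-participant multiplicative
#'   amplitude factor (Normal(1, sd)).
#' @param participant_topography_sd sd (as a fraction of max |pattern|) of
#'   the additive per-participant, per-channel topography perturbation.
#' @param seed integer RNG seed; identical configs give bit-identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants, trials_per_class, class_names,
                       components, mont = fibonacci_montage(32L),
                       sampling_rate = 256, epoch_window = c(0, 0.75),
                       noise_sd = 6, noise_spectral_exponent = 1,
                       latency_jitter_sd = 0.015,
                       participant_amplitude_sd = 0.2,
                       participant_topography_sd = 0.1,
                       seed = 1L) {
  if (!is_count(n_participants)) stopf("n_participants must be a count >= 1")
  if (!is_count(trials_per_class)) stopf("trials_per_class must be a count >= 1")
  class_names <- as.character(class_names)
  if (length(class_names) < 2 || anyDuplicated(class_names)) {
    stopf("class_names must be >= 2 unique names")
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    stopf("sampling_rate must be > 0")
  }
  if (length(epoch_window) != 2 || epoch_window[2] <= epoch_window[1]) {
    stopf("epoch_window must be (start, end) with end > start")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_number(latency_jitter_sd) || latency_jitter_sd < 0) {
    stopf("latency_jitter_sd must be >= 0")
  }
  stopifnot(inherits(mont, "eeg_montage"))
  dur <- epoch_window[2] - epoch_window[1]
  nch <- length(mont$channel_labels)
  for (comp in components) {
    if (!inherits(comp, "component_spec")) stopf("components must be component_specs")
    if (length(comp$spatial_pattern) != nch) {
      stopf("component '%s' has %d pattern weights but montage has %d channels",
            comp$name, length(comp$spatial_pattern), nch)
    }
    if (comp$temporal_width >= dur) {
      stopf("component '%s': temporal_width must be smaller than the epoch",
            comp$name)
    }
    if (comp$peak_latency < epoch_window[1] ||
        comp$peak_latency > epoch_window[2]) {
      stopf("component '%s': peak latency %.3f s outside epoch window [%g, %g]",
            comp$name, comp$peak_latency, epoch_window[1], epoch_window[2])
    }
    unknown <- setdiff(comp$class_selector, class_names)
    if (length(unknown)) {
      stopf("component '%s' targets unknown class(es): %s",
            comp$name, paste(unknown, collapse = ", "))
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_class = as.integer(trials_per_class),
                 class_names = class_names, components = components,
                 montage = mont, sampling_rate = sampling_rate,
                 epoch_window = as.numeric(epoch_window),
                 noise_sd = noise_sd,
                 noise_spectral_exponent = noise_spectral_exponent,
                 latency_jitter_sd = latency_jitter_sd,
                 participant_amplitude_sd = participant_amplitude_sd,
                 participant_topography_sd = participant_topography_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default three-class configuration
#'
#' Emulates a visual-stimulation study: three stimulus classes, each with one
#' evoked component over a distinct posterior/central channel group and a
#' distinct latency in the 0.15-0.23 s range where visual evoked responses
#' peak. Six channels carry each component above the ground-truth threshold.
#'
#' @param n_participants,trials_per_class,seed design size and seed.
#' @param mont montage (default 32-channel Fibonacci lattice).
#' @param ... passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_3class <- function(n_participants = 8, trials_per_class = 50,
                              seed = 1L, mont = fibonacci_montage(32L), ...) {
  comps <- list(
    component_spec(0.15, 0.03, 5,
                   spatial_pattern_around(mont, c(-0.45, -0.85, 0.30)),
                   "A", name = "A-posterior-left"),
    component_spec(0.22, 0.03, 5,
                   spatial_pattern_around(mont, c(0.45, -0.85, 0.30)),
                   "B", name = "B-posterior-right"),
    component_spec(0.19, 0.03, 5,
                   spatial_pattern_around(mont, c(0.00, 0.20, 0.98)),
                   "C", name = "C-central"))
  sim_config(n_participants, trials_per_class, c("A", "B", "C"),
             comps, mont = mont, seed = seed, ...)
}

#' Default two-class pre/post-stimulation configuration
#'
#' Emulates a paradigm where one class is a stimulation-free (pre-stimulus)
#' epoch and the other carries an early fronto-central evoked component, the
#' way an auditory N100 follows tone onset (~0.1 s).
#'
#' @inheritParams sim_config_3class
#' @return A `sim_config`.
#' @export
sim_config_prepost <- function(n_participants = 8, trials_per_class = 100,
                               seed = 1L, mont = fibonacci_montage(32L), ...) {
  comps <- list(
    component_spec(0.10, 0.025, 5,
                   spatial_pattern_around(mont, c(0.00, 0.55, 0.84)),
                   "post", name = "post-frontocentral"))
  sim_config(n_participants, trials_per_class, c("pre", "post"),
             comps, mont = mont, seed = seed, ...)
}

# 1/f^alpha gain per FFT bin, normalized to unit mean power so the shaped
# noise keeps the requested sd
spectral_gain <- function(n_samples, sampling_rate, alpha) {
  freqs <- c(0, seq_len(n_samples - 1)) * sampling_rate / n_samples
  freqs <- pmin(freqs, sampling_rate - freqs)  # two-sided
  f0 <- sampling_rate / n_samples              # lowest nonzero frequency
  gain <- ifelse(freqs < f0, f0, freqs)^(-alpha / 2)
  gain / sqrt(mean(gain^2))
}

# shaped Gaussian noise, channels x samples x n
pink_noise <- function(n_channels, n_samples, n, gain, noise_sd) {
  white <- matrix(rnorm(n_samples * n_channels * n), nrow = n_samples)
  shaped <- Re(mvfft(mvfft(white) * gain, inverse = TRUE)) / n_samples
  # columns of `shaped` are channel-major within trial; rebuild the
  # channel x sample x trial layout explicitly
  out <- array(0, dim = c(n_channels, n_samples, n))
  idx <- 0L
  for (j in seq_len(n)) {
    cols <- (idx + 1L):(idx + n_channels)
    out[, , j] <- t(shaped[, cols, drop = FALSE]) * noise_sd
    idx <- idx + n_channels
  }
  out
}

#' Simulate a multi-participant epoched EEG dataset
#'
#' Generates `n_participants * trials_per_class * n_classes` trials. Each
#' trial is the sum, over the components of its class, of a
#' participant-perturbed spatial pattern times a Gaussian time bump centered
#' at the (per-trial jittered) peak latency, plus 1/f^alpha-shaped Gaussian
#' background noise, followed by common-average re-referencing per sample.
#' Per-participant variability: a multiplicative amplitude factor
#' Normal(1, participant_amplitude_sd) and an additive per-channel topography
#' perturbation Normal(0, participant_topography_sd * max|pattern|), drawn
#' once per participant. Identical configurations (including seed) produce
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @return An [epochs_set()].
#' @examples
#' cfg <- sim_config_3class(n_participants = 2, trials_per_class = 5)
#' ep <- simulate_dataset(cfg)
#' dim(ep$data)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  win <- config$epoch_window
  n_samp <- round((win[2] - win[1]) * fs)
  times <- win[1] + (seq_len(n_samp) - 1) / fs
  nch <- length(config$montage$channel_labels)
  ncl <- length(config$class_names)
  npp <- config$n_participants
  ntr <- config$trials_per_class
  n_total <- npp * ncl * ntr
  gain <- spectral_gain(n_samp, fs, config$noise_spectral_exponent)

  data <- array(0, dim = c(n_total, nch, n_samp))
  labels <- character(n_total)
  participants <- character(n_total)
  pp_ids <- sprintf("P%02d", seq_len(npp))

  with_seed(config$seed, {
    row <- 0L
    for (p in seq_len(npp)) {
      amp_fac <- 1 + rnorm(1) * config$participant_amplitude_sd
      # one perturbed pattern per component, fixed for this participant
      patterns <- lapply(config$components, function(comp) {
        comp$spatial_pattern +
          rnorm(nch) * config$participant_topography_sd *
            max(abs(comp$spatial_pattern))
      })
      for (cl in config$class_names) {
        comp_idx <- which(vapply(config$components,
                                 function(co) cl %in% co$class_selector,
                                 logical(1)))
        signal <- array(0, dim = c(nch, n_samp, ntr))
        for (ci in comp_idx) {
          comp <- config$components[[ci]]
          jit <- rnorm(ntr) * config$latency_jitter_sd
          lo <- win[1] + comp$temporal_width
          hi <- win[2] - comp$temporal_width
          peak <- pmin(pmax(comp$peak_latency + jit, lo), hi)
          pat <- patterns[[ci]] * comp$amplitude * amp_fac
          for (tr in seq_len(ntr)) {
            bump <- exp(-(times - peak[tr])^2 / (2 * comp$temporal_width^2))
            signal[, , tr] <- signal[, , tr] + outer(pat, bump)
          }
        }
        if (config$noise_sd > 0) {
          signal <- signal + pink_noise(nch, n_samp, ntr, gain, config$noise_sd)
        }
        for (tr in seq_len(ntr)) {
          trial <- signal[, , tr]
          trial <- sweep(trial, 2, colMeans(trial))  # common average reference
          row <- row + 1L
          data[row, , ] <- trial
          labels[row] <- cl
          participants[row] <- pp_ids[p]
        }
      }
    }
  })

  epochs_set(data, factor(labels, levels = config$class_names),
             factor(participants, levels = pp_ids), times, config$montage,
             sampling_rate = fs)
}

#' Ground-truth mask for a class
#'
#' Binary channels x samples mask marking where the planted components of a
#' class live: channels with |spatial pattern| > 0.5 and samples within
#' peak latency +/- temporal width, unioned over the class's components.
#' Stimulation-free classes yield an all-zero mask.
#'
#' @param config a [sim_config()].
#' @param class_name one of `config$class_names`.
#' @return Integer 0/1 matrix, channels x samples.
#' @export
ground_truth_mask <- function(config, class_name) {
  stopifnot(inherits(config, "sim_config"))
  if (!class_name %in% config$class_names) {
    stopf("unknown class '%s'", class_name)
  }
  fs <- config$sampling_rate
  win <- config$epoch_window
  n_samp <- round((win[2] - win[1]) * fs)
  times <- win[1] + (seq_len(n_samp) - 1) / fs
  nch <- length(config$montage$channel_labels)
  mask <- matrix(0L, nch, n_samp)
  for (comp in config$components) {
    if (!class_name %in% comp$class_selector) next
    ch <- abs(comp$spatial_pattern) > 0.5
    tt <- abs(times - comp$peak_latency) <= comp$temporal_width
    mask[ch, tt] <- 1L
  }
  mask
}
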