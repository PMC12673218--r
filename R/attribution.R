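#' Attribution map container
#'
#' A channels x samples grid of importance values aligned to the input time
#' axis, tagged with its method, layer, target class, sign convention, and
#' provenance (fold / participant / trial).
#'
#' @param values channels x samples numeric matrix.
#' @param method `"saliency"` or `"gradcam"`.
#' @param layer convolution identifier, or `"input"` for saliency.
#' @param target_class class the score was backpropagated for.
#' @param sign_convention `"signed"` or `"nonnegative"`.
#' @param times sample latencies (seconds).
#' @param channels channel labels.
#' @param fold,participant,trial provenance tags (`"aggregate"` for pooled
#'   maps).
#' @return An object of class `attribution_map`.
#' @export
attribution_map <- function(values, method, layer, target_class,
                            sign_convention, times, channels,
                            fold = NA, participant = NA, trial = NA) {
  values <- as.matrix(values)
  if (nrow(values) != length(channels) || ncol(values) != length(times)) {
    stopf("values must be channels (%d) x samples (%d)",
          length(channels), length(times))
  }
  if (method == "gradcam" && min(values) < 0) {
    stopf("gradcam maps must be elementwise nonnegative")
  }
  structure(list(values = values, method = method, layer = layer,
                 target_class = target_class,
                 sign_convention = sign_convention,
                 times = times, channels = channels,
                 fold = fold, participant = participant, trial = trial),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %s/%s class=%s (%d ch x %d samples, %s)\n",
              x$method, x$layer, x$target_class, nrow(x$values),
              ncol(x$values), x$sign_convention))
  invisible(x)
}

# resample a per-layer time-only map (vector on layer times) onto the input
# channels x samples grid: linear interpolation along time, broadcast
# (nearest-neighbor) across channels
resample_to_input <- function(v, layer_times, times, n_channels) {
  if (length(layer_times) == length(times) &&
      max(abs(layer_times - times)) < 1e-12) {
    row <- v
  } else if (length(layer_times) == 1L) {
    row <- rep(v, length(times))
  } else {
    row <- approx(layer_times, v, xout = times, rule = 2)$y
  }
  matrix(row, n_channels, length(times), byrow = TRUE)
}

#' Saliency map of one trial
#'
#' Gradient of the pre-softmax class score with respect to the input,
#' `d S_c(I) / d I`, evaluated at the trial: the per-channel, per-sample
#' influence on the class score. Trial-level maps are signed; absolute
#' values are taken at aggregation.
#'
#' @param trained a trained decoder.
#' @param trial channels x samples matrix (microvolts).
#' @param target_class class name or index to backpropagate.
#' @param times,channels optional axis annotations for the returned map.
#' @return An [attribution_map()] with `layer = "input"`.
#' @export
saliency_map <- function(trained, trial, target_class, times = NULL,
                         channels = NULL) {
  trial <- as.matrix(trial)
  cls_idx <- class_index(trained, target_class)
  g <- attribution_gradients(trained, array(trial, c(dim(trial), 1)),
                             cls_idx, need_input = TRUE)
  attribution_map(g$dinput[, , 1],
                  method = "saliency", layer = "input",
                  target_class = trained$class_names[cls_idx],
                  sign_convention = "signed",
                  times = times %||% seq_len(ncol(trial)),
                  channels = channels %||% default_channels(trained))
}

#' Grad-CAM map of one trial at a named layer
#'
#' For every feature map `A^k` of the layer, the importance weight is the
#' global average pool of the class-score gradient,
#' `w_k = (1/Z) sum_ij dS_c / dA^k_ij`; the map is
#' `ReLU(sum_k w_k A^k)`, resampled to the input channels x samples grid
#' (linear interpolation along time, nearest-neighbor across the
#' channel/feature axis). A layer whose combined map is all zero (dead
#' gradients) yields a zero map with attribute `dead_layer = TRUE` rather
#' than an error.
#'
#' @inheritParams saliency_map
#' @param layer one of the decoder's `spec$named_layers`.
#' @return A nonnegative [attribution_map()].
#' @export
gradcam_map <- function(trained, trial, target_class, layer, times = NULL,
                        channels = NULL) {
  trial <- as.matrix(trial)
  cls_idx <- class_index(trained, target_class)
  times <- times %||% seq_len(ncol(trial))
  g <- attribution_gradients(trained, array(trial, c(dim(trial), 1)),
                             cls_idx, layers = layer)
  vals <- gradcam_combine(trained, g$layer_acts[[layer]],
                          g$layer_grads[[layer]], layer, times)[, , 1]
  map <- attribution_map(vals, method = "gradcam", layer = layer,
                         target_class = trained$class_names[cls_idx],
                         sign_convention = "nonnegative", times = times,
                         channels = channels %||% default_channels(trained))
  attr(map, "dead_layer") <- all(vals == 0)
  map
}

class_index <- function(trained, target_class) {
  if (is.numeric(target_class)) {
    i <- as.integer(target_class)
    if (i < 1 || i > trained$n_classes) stopf("class index out of range")
    return(i)
  }
  i <- match(as.character(target_class), trained$class_names)
  if (is.na(i)) stopf("unknown class '%s'", target_class)
  i
}

default_channels <- function(trained) paste0("ch", seq_len(trained$n_channels))

# one backward pass per batch: gradients of the pre-softmax score of
# `cls_idx` (scalar or per-trial vector) wrt input and/or layer activations
attribution_gradients <- function(trained, X, cls_idx, need_input = FALSE,
                                  layers = character()) {
  N <- dim(X)[3]
  if (length(cls_idx) == 1L) cls_idx <- rep(cls_idx, N)
  fw <- decoder_forward(trained, X)
  dlogits <- matrix(0, trained$n_classes, N)
  dlogits[cbind(cls_idx, seq_len(N))] <- 1
  bw <- decoder_backward(trained, fw$cache, dlogits,
                         need_input = need_input, layers = layers)
  acts <- setNames(lapply(layers, function(l) {
    layer_activation(trained, fw$cache, l)
  }), layers)
  list(dinput = bw$dinput, layer_grads = bw$layer_grads, layer_acts = acts)
}

# batched Grad-CAM combination. act/grad: (T, M, N) time-only layers or
# (T, F, C, N) for the eegnet channel x time layer. Returns (C, T_in, N).
gradcam_combine <- function(trained, act, grad, layer, times) {
  geo <- layer_geometry(trained, layer, times)
  nd <- length(dim(act))
  if (geo$kind == "chan_time") {            # (T, F, C, N)
    Tn <- dim(act)[1]; Fn <- dim(act)[2]; C <- dim(act)[3]; N <- dim(act)[4]
    out <- array(0, c(C, length(times), N))
    for (n in seq_len(N)) {
      a <- act[, , , n, drop = FALSE]; dim(a) <- c(Tn, Fn, C)
      g <- grad[, , , n, drop = FALSE]; dim(g) <- c(Tn, Fn, C)
      comb <- matrix(0, C, Tn)
      for (f in seq_len(Fn)) {
        w <- mean(g[, f, ])                  # (1/Z) sum over C x T grid
        comb <- comb + w * t(a[, f, ])
      }
      out[, , n] <- pmax(comb, 0)
    }
    out
  } else {                                   # (T_l, M, N)
    Tl <- dim(act)[1]; M <- dim(act)[2]; N <- dim(act)[3]
    C <- trained$n_channels
    out <- array(0, c(C, length(times), N))
    for (n in seq_len(N)) {
      gm <- matrix(grad[, , n], Tl, M)
      am <- matrix(act[, , n], Tl, M)
      w <- colMeans(gm)                      # (1/Z) sum over the map grid
      comb <- pmax(as.numeric(am %*% w), 0)
      out[, , n] <- resample_to_input(comb, geo$times, times, C)
    }
    out
  }
}

#' Indices of correctly predicted trials
#'
#' @param eval an [evaluate_decoder()] result.
#' @return Integer vector of trial indices with correct predictions (empty
#'   if none were correct).
#' @export
select_correct_trials <- function(eval) {
  stopifnot(inherits(eval, "evaluation_result"))
  which(eval$per_trial_correct)
}

#' Trial-level attribution maps for a set of trials
#'
#' Computes saliency or Grad-CAM maps for every requested trial of an
#' epochs set in batches (one forward/backward pass per batch), targeting
#' each trial's true class. Used by the pipeline after correct-trial
#' filtering, where true and predicted class coincide.
#'
#' @param trained a trained decoder.
#' @param epochs an [epochs_set()].
#' @param trials integer trial indices (default all).
#' @param method `"saliency"` or `"gradcam"`.
#' @param layer named layer (gradcam only).
#' @param batch batch size for the backward passes.
#' @return A list of [attribution_map()]s, one per trial, tagged with
#'   participant and trial provenance.
#' @export
attribute_trials <- function(trained, epochs, trials = NULL,
                             method = c("saliency", "gradcam"),
                             layer = NULL, batch = 64L) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "epochs_set"))
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[1])
  if (method == "gradcam" && is.null(layer)) stopf("gradcam needs a layer")
  out <- vector("list", length(trials))
  channels <- epochs$montage$channel_labels
  pos <- 0L
  for (s in seq(1, length(trials), by = batch)) {
    idx <- trials[s:min(s + batch - 1L, length(trials))]
    X <- epochs_input(epochs, idx)
    cls_idx <- match(as.character(epochs$labels[idx]), trained$class_names)
    if (anyNA(cls_idx)) stopf("trial labels outside the decoder's class set")
    if (method == "saliency") {
      g <- attribution_gradients(trained, X, cls_idx, need_input = TRUE)
      for (j in seq_along(idx)) {
        pos <- pos + 1L
        out[[pos]] <- attribution_map(
          g$dinput[, , j], "saliency", "input",
          as.character(epochs$labels[idx[j]]), "signed",
          epochs$times, channels,
          participant = as.character(epochs$participants[idx[j]]),
          trial = idx[j])
      }
    } else {
      g <- attribution_gradients(trained, X, cls_idx, layers = layer)
      vals <- gradcam_combine(trained, g$layer_acts[[layer]],
                              g$layer_grads[[layer]], layer, epochs$times)
      for (j in seq_along(idx)) {
        pos <- pos + 1L
        out[[pos]] <- attribution_map(
          vals[, , j], "gradcam", layer,
          as.character(epochs$labels[idx[j]]), "nonnegative",
          epochs$times, channels,
          participant = as.character(epochs$participants[idx[j]]),
          trial = idx[j])
      }
    }
  }
  out
}

#' Hierarchical aggregation of trial-level maps
#'
#' Averages attribution maps first across trials (within participant), then
#' across participants (within fold), then across folds — in exactly that
#' order, so participants with unequal trial counts weigh equally. Saliency
#' maps are converted to absolute values before averaging, after which the
#' aggregate is nonnegative for both methods. Participants contributing no
#' trials are dropped with a warning.
#'
#' All maps must share method, layer, target class, and grid.
#'
#' @param maps list of trial-level [attribution_map()]s (each tagged with a
#'   participant; fold tags optional, `NA` treated as a single fold).
#' @return List with `aggregate` (an [attribution_map()]),
#'   `per_participant` (channels x samples x participant array, averaged
#'   across folds), and `participants`.
#' @export
aggregate_maps <- function(maps) {
  if (!length(maps)) stopf("no maps to aggregate")
  m0 <- maps[[1]]
  same <- vapply(maps, function(m) {
    identical(m$method, m0$method) && identical(m$layer, m0$layer) &&
      identical(m$target_class, m0$target_class) &&
      all(dim(m$values) == dim(m0$values))
  }, logical(1))
  if (!all(same)) stopf("maps must share method, layer, class, and grid")

  folds <- vapply(maps, function(m) as.character(m$fold %||% NA), character(1))
  folds[is.na(folds)] <- "fold1"
  pps <- vapply(maps, function(m) as.character(m$participant), character(1))
  if (anyNA(pps)) stopf("all maps need a participant tag")
  take <- function(m) if (m0$method == "saliency") abs(m$values) else m$values

  pp_levels <- sort(unique(pps))
  nch <- nrow(m0$values); nt <- ncol(m0$values)
  # trial -> participant mean within each fold
  fold_means <- list()
  pp_sums <- array(0, c(nch, nt, length(pp_levels)))
  pp_counts <- integer(length(pp_levels))
  for (fd in sort(unique(folds))) {
    sel <- which(folds == fd)
    pp_in_fold <- unique(pps[sel])
    pmaps <- lapply(pp_in_fold, function(p) {
      ids <- sel[pps[sel] == p]
      Reduce(`+`, lapply(maps[ids], take)) / length(ids)
    })
    for (j in seq_along(pp_in_fold)) {
      k <- match(pp_in_fold[j], pp_levels)
      pp_sums[, , k] <- pp_sums[, , k] + pmaps[[j]]
      pp_counts[k] <- pp_counts[k] + 1L
    }
    fold_means[[fd]] <- Reduce(`+`, pmaps) / length(pmaps)
  }
  agg <- Reduce(`+`, fold_means) / length(fold_means)
  keep <- pp_counts > 0
  per_pp <- array(0, c(nch, nt, sum(keep)))
  for (j in seq_along(which(keep))) {
    k <- which(keep)[j]
    per_pp[, , j] <- pp_sums[, , k] / pp_counts[k]
  }
  aggregate <- attribution_map(agg, m0$method, m0$layer, m0$target_class,
                               sign_convention = "nonnegative",
                               times = m0$times, channels = m0$channels,
                               fold = "aggregate",
                               participant = "aggregate",
                               trial = "aggregate")
  list(aggregate = aggregate, per_participant = per_pp,
       participants = pp_levels[keep])
}
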