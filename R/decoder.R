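#' Decoder architecture specification
#'
#' Describes one of the three decoder families:
#' \describe{
#'   \item{`eegnet_style`}{three convolutional layers exploiting EEG
#'     structure: a temporal convolution shared across electrodes, a
#'     depthwise spatial convolution spanning all electrodes, and a separable
#'     temporal convolution, each followed by pooling/dropout, then a softmax
#'     head. Defaults follow the printed study values: temporal kernel 16,
#'     separable kernel 64. (The source work prints "dropout rate = 4",
#'     which is not a valid rate; the conventional 0.25 is the default.)}
#'   \item{`residual_small`}{a reduced residual network: an initial
#'     multi-channel temporal convolution, `residual_blocks` two-convolution
#'     blocks with identity (or 1x1 projection) shortcuts widening from
#'     `n_filters` to `2 * n_filters`, global average pooling, softmax head.}
#'   \item{`logistic_pointwise`}{marker for the time-point-wise multinomial
#'     logistic baseline; see [pointwise_logreg_baseline()].}
#' }
#'
#' @param family one of `"eegnet_style"`, `"residual_small"`,
#'   `"logistic_pointwise"`.
#' @param temporal_kernel_length first-layer temporal kernel, samples.
#' @param spatial_depth_multiplier depthwise multiplier of the spatial
#'   convolution (eegnet_style).
#' @param separable_kernel_length separable-layer kernel, samples.
#' @param n_filters first-layer filter count (eegnet_style: temporal filters;
#'   residual_small: base width).
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param residual_blocks number of residual blocks (residual_small).
#' @param pool_sizes length-2 pooling factors after the spatial and separable
#'   stages (eegnet_style).
#' @return An object of class `architecture_spec` with a `named_layers`
#'   element listing the attribution-eligible convolution identifiers.
#' @export
architecture_spec <- function(family = c("eegnet_style", "residual_small",
                                         "logistic_pointwise"),
                              temporal_kernel_length = 16L,
                              spatial_depth_multiplier = 2L,
                              separable_kernel_length = 64L,
                              n_filters = NULL,
                              dropout_rate = 0.25,
                              residual_blocks = 4L,
                              pool_sizes = c(2L, 4L)) {
  family <- match.arg(family)
  if (is.null(n_filters)) {
    n_filters <- if (family == "residual_small") 16L else 8L
  }
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stopf("dropout_rate must be in [0, 1)")
  }
  for (k in c(temporal_kernel_length, separable_kernel_length, n_filters)) {
    if (!is_count(k)) stopf("kernel lengths and filter counts must be counts")
  }
  named_layers <- switch(family,
    eegnet_style = c("conv1", "conv2", "conv3"),
    residual_small = c("conv1", paste0("block", seq_len(residual_blocks))),
    logistic_pointwise = character())
  structure(list(family = family,
                 temporal_kernel_length = as.integer(temporal_kernel_length),
                 spatial_depth_multiplier = as.integer(spatial_depth_multiplier),
                 separable_kernel_length = as.integer(separable_kernel_length),
                 n_filters = as.integer(n_filters),
                 dropout_rate = dropout_rate,
                 residual_blocks = as.integer(residual_blocks),
                 pool_sizes = as.integer(pool_sizes),
                 named_layers = named_layers),
            class = "architecture_spec")
}

#' Early / intermediate / late layer presets
#'
#' Maps the three canonical attribution depths to concrete layer identifiers
#' of a family: for the three-layer `eegnet_style` network these are its
#' three convolutions; for `residual_small` the initial convolution, a
#' mid-depth block, and the deepest block.
#'
#' @param spec an [architecture_spec()].
#' @return Named character vector with entries `early`, `intermediate`,
#'   `late`.
#' @export
layer_presets <- function(spec) {
  nl <- spec$named_layers
  if (spec$family == "eegnet_style") {
    c(early = "conv1", intermediate = "conv2", late = "conv3")
  } else {
    c(early = nl[1],
      intermediate = nl[1 + max(1L, spec$residual_blocks %/% 2L)],
      late = nl[length(nl)])
  }
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build an untrained decoder
#'
#' Instantiates seeded initial parameters for an input of `n_channels` x
#' `n_samples` and `n_classes` output classes. A forward pass on any input
#' returns softmax probabilities summing to 1.
#'
#' @param spec an [architecture_spec()].
#' @param n_channels,n_samples input grid.
#' @param n_classes number of classes.
#' @param class_names optional class names (default `"class1"` ...).
#' @param seed RNG seed for parameter initialization.
#' @return An object of class `eeg_decoder`.
#' @export
build_decoder <- function(spec, n_channels, n_samples, n_classes,
                          class_names = NULL, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$family == "logistic_pointwise") {
    stopf("the logistic baseline has no network; use pointwise_logreg_baseline()")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  stopifnot(length(class_names) == n_classes)
  C <- as.integer(n_channels); T <- as.integer(n_samples)
  params <- with_seed(seed, {
    if (spec$family == "eegnet_style") {
      k1 <- spec$temporal_kernel_length
      k3 <- spec$separable_kernel_length
      F1 <- spec$n_filters
      F2 <- F1 * spec$spatial_depth_multiplier
      F3 <- F2
      p1 <- spec$pool_sizes[1]; p2 <- spec$pool_sizes[2]
      T1 <- T %/% p1
      T2 <- T1 %/% p2
      if (k1 > T) stopf("temporal kernel (%d) longer than input (%d)", k1, T)
      if (k3 > T1) {
        stopf("separable kernel (%d) longer than pooled input (%d)", k3, T1)
      }
      if (T2 < 1) stopf("pooling leaves no samples")
      list(W1 = he_uniform(c(k1, 1, F1), k1),
           b1 = numeric(F1),
           W2 = he_uniform(c(C, F2), C),
           b2 = numeric(F2),
           W3d = he_uniform(c(k3, F2), k3),
           W3p = he_uniform(c(F2, F3), F2),
           b3 = numeric(F3),
           W4 = he_uniform(c(T2 * F3, n_classes), T2 * F3),
           b4 = numeric(n_classes))
    } else {
      k <- spec$temporal_kernel_length
      if (k > T) stopf("temporal kernel (%d) longer than input (%d)", k, T)
      F1 <- spec$n_filters
      B <- spec$residual_blocks
      widen_at <- if (B >= 3) B - 1L else B + 1L  # widen at the penultimate block
      p <- list(W0 = he_uniform(c(k, C, F1), k * C), b0 = numeric(F1))
      fin <- F1
      for (b in seq_len(B)) {
        fout <- if (b >= widen_at) 2L * F1 else F1
        p[[paste0("blk", b, "_Wa")]] <- he_uniform(c(k, fin, fout), k * fin)
        p[[paste0("blk", b, "_ba")]] <- numeric(fout)
        p[[paste0("blk", b, "_Wb")]] <- he_uniform(c(k, fout, fout), k * fout)
        p[[paste0("blk", b, "_bb")]] <- numeric(fout)
        if (fout != fin) {
          p[[paste0("blk", b, "_Wp")]] <- he_uniform(c(1, fin, fout), fin)
        }
        fin <- fout
      }
      p$Wd <- he_uniform(c(fin, n_classes), fin)
      p$bd <- numeric(n_classes)
      p
    }
  })
  structure(list(spec = spec, params = params,
                 n_channels = C, n_samples = T,
                 n_classes = as.integer(n_classes),
                 class_names = as.character(class_names),
                 input_scale = 1,
                 seed = as.integer(seed)),
            class = "eeg_decoder")
}

#' @export
print.eeg_decoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<eeg_decoder> %s: %d ch x %d samples -> %d classes (%d parameters)\n",
              x$spec$family, x$n_channels, x$n_samples, x$n_classes, np))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs (best val loss %.4f @ epoch %d)\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  }
  invisible(x)
}

#' Total trainable parameter count
#' @param decoder an `eeg_decoder`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(decoder) {
  sum(vapply(decoder$params, length, integer(1)))
}

elu <- function(x) {
  i <- which(x < 0)
  if (length(i)) x[i] <- exp(x[i]) - 1
  x
}
elu_grad <- function(x) {
  g <- array(1, dim(x))
  i <- which(x < 0)
  if (length(i)) g[i] <- exp(x[i])
  g
}
relu <- function(x) pmax(x, 0)

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# average-pool (T, M, N) -> (T1, M, N) over non-overlapping windows of p,
# dropping trailing samples
pool_time <- function(a, p) {
  d <- dim(a)
  T1 <- d[1] %/% p
  a <- a[seq_len(T1 * p), , , drop = FALSE]
  m <- colMeans(array(a, c(p, T1 * d[2] * d[3])))
  array(m, c(T1, d[2], d[3]))
}

# adjoint of pool_time: spread gradient back over the window
unpool_time <- function(g, p, T_full) {
  d <- dim(g)
  out <- array(0, c(T_full, d[2], d[3]))
  idx <- rep(seq_len(d[1]), each = p)
  out[seq_along(idx), , ] <- g[idx, , , drop = FALSE] / p
  out
}

dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

# ---- EEGNet-style forward / backward -------------------------------------
# thin wrappers over the fused C++ kernels; see src/eegnet_kernels.cpp for
# the memory layouts

eegnet_forward <- function(dec, X, training = FALSE) {
  sp <- dec$spec; pa <- dec$params
  C <- dim(X)[1]; T <- dim(X)[2]; N <- dim(X)[3]
  F1 <- sp$n_filters; D <- sp$spatial_depth_multiplier
  F2 <- F1 * D; F3 <- F2
  p1 <- sp$pool_sizes[1]; p2 <- sp$pool_sizes[2]
  T1 <- T %/% p1; T2 <- T1 %/% p2
  Xs <- aperm(X, c(1, 3, 2)); dim(Xs) <- c(C * N, T)
  W1m <- pa$W1; dim(W1m) <- c(dim(pa$W1)[1], F1)
  none <- matrix(1, 1, 1)
  drop1 <- if (training && sp$dropout_rate > 0) {
    matrix((runif(F2 * N * T1) >= sp$dropout_rate) / (1 - sp$dropout_rate),
           F2 * N, T1)
  } else none
  drop2 <- if (training && sp$dropout_rate > 0) {
    matrix((runif(F3 * N * T2) >= sp$dropout_rate) / (1 - sp$dropout_rate),
           F3 * N, T2)
  } else none
  fw <- eegnet_fw_cpp(Xs, C, N, W1m, pa$b1, pa$W2, pa$b2, D, pa$W3d,
                      pa$W3p, pa$b3, pa$W4, pa$b4, p1, p2, drop1, drop2)
  fw$Xs <- Xs
  fw$drop1 <- drop1; fw$drop2 <- drop2
  fw$dims <- c(C = C, T = T, N = N, F1 = F1, F2 = F2, F3 = F3,
               T1 = T1, T2 = T2, p1 = p1, p2 = p2)
  list(logits = fw$logits, probs = fw$probs, cache = fw)
}

eegnet_backward <- function(dec, cache, dlogits, need_input = FALSE,
                            layers = character()) {
  sp <- dec$spec; pa <- dec$params
  d <- as.list(cache$dims)
  W1m <- pa$W1; dim(W1m) <- c(dim(pa$W1)[1], d$F1)
  bw <- eegnet_bw_cpp(cache$Xs, d$C, d$N, W1m, pa$W2,
                      sp$spatial_depth_multiplier, pa$W3d, pa$W3p, pa$W4,
                      d$p1, d$p2, cache$drop1, cache$drop2,
                      cache$A1, cache$out2pre, cache$P1, cache$dw,
                      cache$out3pre, cache$P2, dlogits, need_input,
                      "conv1" %in% layers, "conv2" %in% layers,
                      "conv3" %in% layers)
  dW1 <- bw$dW1; dim(dW1) <- dim(pa$W1)
  grads <- list(W1 = dW1, b1 = as.numeric(bw$db1), W2 = bw$dW2,
                b2 = as.numeric(bw$db2), W3d = bw$dW3d, W3p = bw$dW3p,
                b3 = as.numeric(bw$db3), W4 = bw$dW4,
                b4 = as.numeric(bw$db4))
  layer_grads <- list()
  if ("conv1" %in% layers) {
    layer_grads$conv1 <- aperm(array(bw$dA1, c(d$C, d$N, d$T, d$F1)),
                               c(3, 4, 1, 2))          # (T, F1, C, N)
  }
  if ("conv2" %in% layers) {
    layer_grads$conv2 <- aperm(array(bw$da2, c(d$F2, d$N, d$T)),
                               c(3, 1, 2))             # (T, F2, N)
  }
  if ("conv3" %in% layers) {
    layer_grads$conv3 <- aperm(array(bw$da3, c(d$F3, d$N, d$T1)),
                               c(3, 1, 2))             # (T1, F3, N)
  }
  dinput <- NULL
  if (need_input) {
    dinput <- aperm(array(bw$dXs, c(d$C, d$N, d$T)), c(1, 3, 2))
  }
  list(grads = grads, dinput = dinput, layer_grads = layer_grads)
}

# ---- reduced residual network forward / backward -------------------------

resnet_forward <- function(dec, X, training = FALSE) {
  pa <- dec$params; B <- dec$spec$residual_blocks
  Xr <- aperm(X, c(2, 1, 3))                       # (T, C, N)
  A0pre <- cc_conv1d_fw(Xr, pa$W0, pa$b0)
  A0 <- relu(A0pre)
  h <- A0
  blocks <- vector("list", B)
  for (b in seq_len(B)) {
    Wa <- pa[[paste0("blk", b, "_Wa")]]
    Wb <- pa[[paste0("blk", b, "_Wb")]]
    Wp <- pa[[paste0("blk", b, "_Wp")]]
    Za <- cc_conv1d_fw(h, Wa, pa[[paste0("blk", b, "_ba")]])
    Ra <- relu(Za)
    Zb <- cc_conv1d_fw(Ra, Wb, pa[[paste0("blk", b, "_bb")]])
    short <- if (is.null(Wp)) h else {
      cc_conv1d_fw(h, Wp, numeric(dim(Wp)[3]))
    }
    S <- Zb + short
    out <- relu(S)
    blocks[[b]] <- list(hin = h, Za = Za, Ra = Ra, S = S, out = out,
                        proj = !is.null(Wp))
    h <- out
  }
  g <- colMeans(h)                                 # (F, N)
  if (is.null(dim(g))) g <- matrix(g, ncol = dim(h)[3])
  logits <- crossprod(pa$Wd, g) + pa$bd
  probs <- softmax_cols(logits)
  list(logits = logits, probs = probs,
       cache = list(Xr = Xr, A0pre = A0pre, A0 = A0, blocks = blocks, g = g,
                    Tn = dim(Xr)[1]))
}

resnet_backward <- function(dec, cache, dlogits, need_input = FALSE,
                            layers = character()) {
  pa <- dec$params; B <- dec$spec$residual_blocks
  Tn <- cache$Tn
  layer_grads <- list()
  last <- cache$blocks[[B]]$out
  dWd <- cache$g %*% t(dlogits)
  dbd <- rowSums(dlogits)
  dg <- pa$Wd %*% dlogits                          # (F, N)
  dh <- array(0, dim = dim(last))
  for (n in seq_len(dim(last)[3])) {
    dh[, , n] <- matrix(dg[, n], Tn, nrow(dg), byrow = TRUE) / Tn
  }
  grads <- list(Wd = dWd, bd = dbd)
  for (b in rev(seq_len(B))) {
    bk <- cache$blocks[[b]]
    lname <- paste0("block", b)
    if (lname %in% layers) layer_grads[[lname]] <- dh
    dS <- dh * (bk$S > 0)
    bwb <- cc_conv1d_bw(bk$Ra, pa[[paste0("blk", b, "_Wb")]], dS, TRUE)
    grads[[paste0("blk", b, "_Wb")]] <- bwb$dW
    grads[[paste0("blk", b, "_bb")]] <- as.numeric(bwb$db)
    dZa <- bwb$dX * (bk$Za > 0)
    bwa <- cc_conv1d_bw(bk$hin, pa[[paste0("blk", b, "_Wa")]], dZa, TRUE)
    grads[[paste0("blk", b, "_Wa")]] <- bwa$dW
    grads[[paste0("blk", b, "_ba")]] <- as.numeric(bwa$db)
    dh_new <- bwa$dX
    if (bk$proj) {
      Wp <- pa[[paste0("blk", b, "_Wp")]]
      bwp <- cc_conv1d_bw(bk$hin, Wp, dS, TRUE)
      grads[[paste0("blk", b, "_Wp")]] <- bwp$dW
      dh_new <- dh_new + bwp$dX
    } else {
      dh_new <- dh_new + dS
    }
    dh <- dh_new
  }
  if ("conv1" %in% layers) layer_grads$conv1 <- dh
  dA0pre <- dh * (cache$A0pre > 0)
  bw0 <- cc_conv1d_bw(cache$Xr, pa$W0, dA0pre, need_input)
  grads$W0 <- bw0$dW
  grads$b0 <- as.numeric(bw0$db)
  dinput <- if (need_input) aperm(bw0$dX, c(2, 1, 3)) else NULL
  list(grads = grads, dinput = dinput, layer_grads = layer_grads)
}

# ---- family dispatch ------------------------------------------------------

decoder_forward <- function(dec, X, training = FALSE) {
  if (dim(X)[1] != dec$n_channels || dim(X)[2] != dec$n_samples) {
    stopf("input is %d x %d but decoder expects %d x %d",
          dim(X)[1], dim(X)[2], dec$n_channels, dec$n_samples)
  }
  sc <- dec$input_scale %||% 1
  if (sc != 1) X <- X * sc
  switch(dec$spec$family,
         eegnet_style = eegnet_forward(dec, X, training),
         resnet_forward(dec, X, training))
}

decoder_backward <- function(dec, cache, dlogits, need_input = FALSE,
                             layers = character()) {
  out <- switch(dec$spec$family,
         eegnet_style = eegnet_backward(dec, cache, dlogits, need_input, layers),
         resnet_backward(dec, cache, dlogits, need_input, layers))
  sc <- dec$input_scale %||% 1
  if (need_input && sc != 1) out$dinput <- out$dinput * sc
  out
}

# geometry of a named layer's activation: per-trial feature maps and the
# time axis they live on
layer_geometry <- function(dec, layer, times) {
  sp <- dec$spec
  if (!layer %in% sp$named_layers) {
    stopf("layer '%s' is not one of: %s", layer,
          paste(sp$named_layers, collapse = ", "))
  }
  if (sp$family == "eegnet_style") {
    p1 <- sp$pool_sizes[1]
    T1 <- dec$n_samples %/% p1
    switch(layer,
      conv1 = list(kind = "chan_time", times = times),
      conv2 = list(kind = "time_only", times = times),
      conv3 = list(kind = "time_only",
                   times = colMeans(matrix(times[seq_len(p1 * T1)], p1))))
  } else {
    list(kind = "time_only", times = times)
  }
}

# pull the activation array of a named layer out of a forward cache:
# eegnet conv1 -> (T, F1, C, N); others -> (T, M, N)
layer_activation <- function(dec, cache, layer) {
  if (dec$spec$family == "eegnet_style") {
    d <- as.list(cache$dims)
    switch(layer,
      conv1 = aperm(array(cache$A1, c(d$C, d$N, d$T, d$F1)), c(3, 4, 1, 2)),
      conv2 = aperm(array(cache$a2, c(d$F2, d$N, d$T)), c(3, 1, 2)),
      conv3 = aperm(array(cache$a3, c(d$F3, d$N, d$T1)), c(3, 1, 2)))
  } else {
    if (layer == "conv1") cache$A0
    else cache$blocks[[as.integer(sub("block", "", layer))]]$out
  }
}
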