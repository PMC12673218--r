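# Shared fixtures and independent oracles.

# tiny architecture specs so gradient oracles stay under 1e4 parameters
tiny_eegnet_spec <- function() {
  architecture_spec("eegnet_style", temporal_kernel_length = 5,
                    separable_kernel_length = 7, n_filters = 2,
                    spatial_depth_multiplier = 2, pool_sizes = c(2, 2))
}

tiny_resnet_spec <- function() {
  architecture_spec("residual_small", temporal_kernel_length = 5,
                    n_filters = 4, residual_blocks = 2)
}

# a small fast simulation used across tests
tiny_sim <- function(n_participants = 4, trials_per_class = 8, seed = 11,
                     ...) {
  sim_config_3class(n_participants = n_participants,
                    trials_per_class = trials_per_class, seed = seed, ...)
}

# exact two-sided one-sample signed-rank p-value by enumerating all 2^n sign
# assignments (ties allowed; zeros must be removed by the caller)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  stats <- vapply(seq_len(2^n) - 1L, function(bits) {
    signs <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1L)))
    sum(r[signs])
  }, numeric(1))
  mean(abs(stats - mu) >= abs(v_obs - mu) - 1e-12)
}

# central finite-difference gradient of the pre-softmax class score wrt the
# input of a decoder, at selected elements. Returns the estimate at eps and
# at eps/2: where the two disagree the loss surface is locally non-smooth
# (a ReLU kink sits inside the stencil) and the FD value is not a valid
# oracle, so callers compare only at step-halving-consistent points.
fd_saliency <- function(dec, trial, cls, elements, eps = 1e-3) {
  f <- function(x) {
    X <- array(x, c(dim(trial), 1))
    eeginterp:::decoder_forward(dec, X)$logits[cls, 1]
  }
  one <- function(i, e) {
    xp <- trial; xp[i] <- xp[i] + e
    xm <- trial; xm[i] <- xm[i] - e
    (f(xp) - f(xm)) / (2 * e)
  }
  g1 <- vapply(elements, one, numeric(1), e = eps)
  g2 <- vapply(elements, one, numeric(1), e = eps / 2)
  list(fd = g1, smooth = abs(g1 - g2) <= 1e-6 + 1e-4 * pmax(abs(g1), 1))
}
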