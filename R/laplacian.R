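#' Surface Laplacian parameters
#'
#' @param lambda2 smoothing regularization added to the diagonal of the
#'   spline matrix (> 0; default 1e-5).
#' @param stiffness spline stiffness exponent m (> 2; default 4.7). Larger
#'   values give smoother interpolants.
#' @param n_legendre number of Legendre terms in the spline kernels.
#' @return An object of class `laplacian_params`.
#' @export
laplacian_params <- function(lambda2 = 1e-5, stiffness = 4.7,
                             n_legendre = 50L) {
  if (!is_number(lambda2) || lambda2 <= 0) stopf("lambda2 must be > 0")
  if (!is_number(stiffness) || stiffness <= 2) stopf("stiffness must be > 2")
  structure(list(lambda2 = lambda2, stiffness = stiffness,
                 n_legendre = as.integer(n_legendre)),
            class = "laplacian_params")
}

# P_n(x) for n = 1..nmax at each x, via the Bonnet recurrence;
# returns matrix length(x) x nmax
legendre_table <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      out[, n] <- pn
      pm1 <- p; p <- pn
    }
  }
  out
}

# spherical-spline kernel matrices (Perrin-style): G for interpolation,
# H for the surface Laplacian, evaluated at cosines of inter-electrode angles
spline_matrices <- function(positions, params) {
  cosang <- tcrossprod(positions)
  cosang <- pmin(1, pmax(-1, cosang))
  n <- seq_len(params$n_legendre)
  m <- params$stiffness
  gcoef <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  # positive-at-source (CSD) sign convention
  hcoef <- (2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)
  P <- legendre_table(as.numeric(cosang), params$n_legendre)
  G <- matrix(P %*% gcoef, nrow(positions))
  H <- matrix(P %*% hcoef, nrow(positions))
  list(G = G, H = H)
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Transforms scalp topographies into current-source-density-like maps by
#' fitting a spherical spline to each sample's topography and applying the
#' surface Laplacian of the spline. Spatially constant topographies map to
#' (numerically) zero; the transform is linear and commutes with channel
#' relabeling.
#'
#' @param x channels x samples matrix (a topography per column), or a single
#'   topography vector.
#' @param mont electrode [montage()] (positions on the unit sphere; duplicate
#'   positions are rejected).
#' @param params a [laplacian_params()].
#' @return Transformed map with the same shape as `x`.
#' @export
surface_laplacian <- function(x, mont, params = laplacian_params()) {
  stopifnot(inherits(mont, "eeg_montage"), inherits(params, "laplacian_params"))
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  nch <- nrow(X)
  if (nch != nrow(mont$positions)) {
    stopf("map has %d channels but montage has %d", nch, nrow(mont$positions))
  }
  d <- as.matrix(dist(mont$positions))
  diag(d) <- Inf
  if (min(d) < 1e-9) stopf("duplicate electrode positions in the montage")

  sm <- spline_matrices(mont$positions, params)
  Gs <- sm$G + diag(params$lambda2, nch)
  Gi <- solve(Gs)
  ones <- rep(1, nch)
  gi1 <- Gi %*% ones
  denom <- as.numeric(crossprod(ones, gi1))
  # fit spline coefficients with the zero-sum constraint, then apply H
  c0 <- crossprod(gi1, X) / denom            # 1 x samples
  Cc <- Gi %*% (X - ones %*% c0)             # channels x samples
  out <- sm$H %*% Cc
  if (vec_in) as.numeric(out) else out
}
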