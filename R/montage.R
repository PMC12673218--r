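#' Electrode montage
#'
#' A montage holds unique channel labels and unit-sphere 3-D positions for
#' every channel. Positions are dimensionless direction vectors on the scalp
#' sphere; they are used by the spherical-spline surface Laplacian and for
#' constructing spatial patterns in the simulator.
#'
#' @param channel_labels character vector of unique channel identifiers.
#' @param positions numeric matrix (channels x 3); every row must have unit
#'   Euclidean norm (tolerance 1e-9).
#' @return An object of class `eeg_montage` with elements `channel_labels`
#'   and `positions`.
#' @examples
#' m <- fibonacci_montage(16)
#' print(m)
#' @export
montage <- function(channel_labels, positions) {
  channel_labels <- as.character(channel_labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_labels)) stopf("montage channel labels must be unique")
  if (nrow(positions) != length(channel_labels) || ncol(positions) != 3L) {
    stopf("positions must be a %d x 3 matrix", length(channel_labels))
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stopf("montage positions must lie on the unit sphere (max |norm - 1| = %.3g)",
          max(abs(nrm - 1)))
  }
  rownames(positions) <- channel_labels
  structure(list(channel_labels = channel_labels, positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s ...\n",
              length(x$channel_labels),
              paste(head(x$channel_labels, 6), collapse = ", ")))
  invisible(x)
}

#' Default upper-hemisphere montage on a Fibonacci lattice
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper unit
#' hemisphere (z >= 0) using a golden-angle spiral, the way idealized caps
#' are laid out when real digitized coordinates are not needed. Labels carry
#' a coarse scalp-region prefix (Fp/F/C/P/O frontal to occipital along y,
#' with a z suffix for midline, L/R otherwise) so that simulated topographies
#' read naturally.
#'
#' @param n_channels number of electrodes (>= 8 so the surface Laplacian is
#'   well posed).
#' @return An `eeg_montage`.
#' @export
fibonacci_montage <- function(n_channels = 32L) {
  if (!is_count(n_channels) || n_channels < 8) {
    stopf("n_channels must be an integer >= 8")
  }
  n <- as.integer(n_channels)
  i <- seq_len(n)
  # z strictly positive and away from the rim so no electrode sits on the
  # equator or pole exactly
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (i - 1)
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  # region from the anterior-posterior (y) coordinate
  region <- cut(pos[, "y"], breaks = c(-1.01, -0.55, -0.2, 0.2, 0.55, 1.01),
                labels = c("O", "P", "C", "F", "Fp"))
  side <- ifelse(abs(pos[, "x"]) < 0.15, "z", ifelse(pos[, "x"] < 0, "L", "R"))
  labels <- sprintf("%s%02d%s", as.character(region), i, side)
  montage(labels, pos)
}

#' Read / write a montage as CSV
#'
#' The CSV dialect is `label,x,y,z` with a header row.
#'
#' @param x an `eeg_montage`.
#' @param path file path.
#' @return `read_montage_csv` returns an `eeg_montage`; `write_montage_csv`
#'   returns `path` invisibly.
#' @export
write_montage_csv <- function(x, path) {
  stopifnot(inherits(x, "eeg_montage"))
  df <- data.frame(label = x$channel_labels,
                   x = x$positions[, 1], y = x$positions[, 2],
                   z = x$positions[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stopf("montage CSV must have columns %s", paste(need, collapse = ", "))
  }
  montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}

# great-circle nearest channels to a target direction (unit vector)
nearest_channels <- function(mont, target, n) {
  target <- target / sqrt(sum(target^2))
  d <- acos(pmin(1, pmax(-1, mont$positions %*% target)))
  order(d)[seq_len(n)]
}
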