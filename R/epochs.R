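#' Epoched EEG container
#'
#' An `epochs_set` bundles a trials x channels x samples array of epoched EEG
#' (microvolts) with per-trial class labels, per-trial participant
#' identifiers, the sample time axis (seconds relative to stimulus onset),
#' and the electrode montage.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels per-trial class labels (coerced to factor).
#' @param participants per-trial participant identifiers (coerced to factor).
#' @param times numeric vector of sample latencies in seconds; must be
#'   strictly increasing and uniformly spaced.
#' @param montage an [montage()] whose channel count matches `dim(data)[2]`.
#' @param sampling_rate sampling rate in Hz; defaults to `1/diff(times)[1]`.
#' @return An object of class `epochs_set`.
#' @export
epochs_set <- function(data, labels, participants, times, montage,
                       sampling_rate = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("data must be a trials x channels x samples array")
  }
  n <- dim(data)[1]
  labels <- as.factor(labels)
  participants <- as.factor(participants)
  if (length(labels) != n || length(participants) != n) {
    stopf("labels (%d) and participants (%d) must match trial count (%d)",
          length(labels), length(participants), n)
  }
  if (length(times) != dim(data)[3]) {
    stopf("times length (%d) must equal sample count (%d)",
          length(times), dim(data)[3])
  }
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9)) {
    stopf("times must be strictly increasing and uniformly spaced")
  }
  if (!inherits(montage, "eeg_montage")) stopf("montage must be an eeg_montage")
  if (length(montage$channel_labels) != dim(data)[2]) {
    stopf("montage has %d channels but data has %d",
          length(montage$channel_labels), dim(data)[2])
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / dt[1]
  structure(list(data = data, labels = labels, participants = participants,
                 times = as.numeric(times), montage = montage,
                 sampling_rate = sampling_rate),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  cat(sprintf(
    "<epochs_set> %d trials x %d channels x %d samples @ %g Hz\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate))
  cat(sprintf("  classes: %s\n", paste(levels(x$labels), collapse = ", ")))
  cat(sprintf("  participants: %d (%s ...)\n", nlevels(x$participants),
              paste(head(levels(x$participants), 4), collapse = ", ")))
  cat(sprintf("  time: %.3f .. %.3f s\n", x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Subset an epochs set by trial index
#'
#' @param x an `epochs_set`.
#' @param trials integer or logical trial index.
#' @return An `epochs_set` with the selected trials (factor levels are kept).
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "epochs_set"))
  epochs_set(x$data[trials, , , drop = FALSE],
             x$labels[trials], x$participants[trials],
             x$times, x$montage, x$sampling_rate)
}

#' Subset an epochs set by participant
#'
#' @param x an `epochs_set`.
#' @param participants character vector of participant identifiers to keep.
#' @return An `epochs_set` restricted to those participants.
#' @export
subset_participants <- function(x, participants) {
  stopifnot(inherits(x, "epochs_set"))
  keep <- x$participants %in% participants
  if (!any(keep)) stopf("no trials left after participant subset")
  subset_trials(x, keep)
}

# trials x channels x samples -> (channels, samples, trials), the layout the
# decoders consume
epochs_input <- function(x, trials = NULL) {
  d <- if (is.null(trials)) x$data else x$data[trials, , , drop = FALSE]
  aperm(d, c(2, 3, 1))
}
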