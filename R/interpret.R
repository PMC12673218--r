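#' Interpretability time course of one participant
#'
#' At each sample, the Pearson correlation across channels between the
#' absolute amplitude of the participant's averaged EEG and the (nonnegative)
#' aggregated feature map. Samples where either vector is constant across
#' channels have no defined correlation and are returned as `NA` (excluded
#' from maxima rather than set to 0).
#'
#' @param participant_eeg_mean channels x samples matrix: the participant's
#'   averaged EEG (microvolts).
#' @param participant_feature channels x samples nonnegative feature map on
#'   the same grid.
#' @return Numeric vector of per-sample correlations in `[-1, 1]` (or `NA`).
#' @export
interpretability_timecourse <- function(participant_eeg_mean,
                                        participant_feature) {
  e <- as.matrix(participant_eeg_mean)
  f <- as.matrix(participant_feature)
  if (!all(dim(e) == dim(f))) stopf("EEG and feature grids must match")
  if (nrow(e) < 3) stopf("need >= 3 channels for a channel-wise correlation")
  if (min(f) < 0) stopf("feature map must be nonnegative (aggregate maps)")
  ae <- abs(e)
  vapply(seq_len(ncol(e)), function(t) {
    x <- ae[, t]; y <- f[, t]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
}

# exact two-sided signed-rank p under the null that each rank enters the
# positive sum with probability 1/2: build the distribution of V by
# polynomial convolution over doubled ranks (integers even with midranks),
# so tied absolute values are handled exactly
exact_signed_rank_p <- function(r, V) {
  r2 <- round(2 * r)
  total <- sum(r2)
  counts <- numeric(total + 1)         # index s+1 = count of subsets with sum s
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  mu2 <- total / 2
  dev <- abs(2 * V - mu2)
  s <- seq_along(counts) - 1
  sum(counts[abs(s - mu2) >= dev - 1e-9]) / 2^length(r2)
}

# one-sample Wilcoxon signed rank vs 0. Zeros discarded; exact p (by full
# enumeration of the signed-rank null, ties included) for n <= 25, normal
# approximation with continuity and tie correction above. Returns z and p.
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = 0, p = 1, n = 0L, V = NA_real_))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  sig <- sqrt(sig2)
  cc <- if (V == mu) 0 else 0.5 * sign(V - mu)
  z <- if (sig == 0) 0 else (V - mu - cc) / sig
  if (n <= exact_max) {
    p <- exact_signed_rank_p(r, V)
  } else if (sig == 0) {
    p <- 1
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(z = z, p = p, n = n, V = V)
}

#' Group-level significance of interpretability time courses
#'
#' Tests the per-participant correlations against zero at every sample with
#' a two-sided one-sample Wilcoxon signed-rank test, then controls the false
#' discovery rate across samples with Benjamini-Hochberg. Zero differences
#' are discarded (a sample where all participants have r = 0 gets p = 1).
#'
#' @param timecourses participants x samples matrix of correlations (`NA`s
#'   allowed; participants with `NA` at a sample are dropped there).
#' @param alpha FDR level (default 0.05).
#' @return List with `p_raw`, `p_adjusted`, and logical `group_mask`
#'   (`TRUE` where adjusted p < alpha).
#' @export
group_significance <- function(timecourses, alpha = 0.05) {
  tc <- as.matrix(timecourses)
  if (nrow(tc) < 5) stopf("need >= 5 participants for group statistics")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must be in (0, 1)")
  }
  p_raw <- vapply(seq_len(ncol(tc)), function(s) {
    wilcoxon_signed_rank(tc[, s])$p
  }, numeric(1))
  p_adj <- p.adjust(p_raw, method = "BH")
  list(p_raw = p_raw, p_adjusted = p_adj, group_mask = p_adj < alpha,
       alpha = alpha)
}

#' Maximum interpretability score and its latency
#'
#' @param r_timecourse per-sample correlations (`NA` = undefined, excluded).
#' @param times sample latencies in seconds, same length.
#' @return List with `max_score` and `max_latency` (earliest time on ties).
#' @export
max_score_and_latency <- function(r_timecourse, times) {
  if (length(r_timecourse) != length(times)) {
    stopf("r_timecourse and times must have equal length")
  }
  ok <- !is.na(r_timecourse)
  if (!any(ok)) stopf("all samples undefined; no maximum exists")
  mx <- max(r_timecourse[ok])
  idx <- which(ok & r_timecourse == mx)[1]   # earliest time on ties
  list(max_score = mx, max_latency = times[idx])
}

#' Paired Wilcoxon comparison of two score vectors
#'
#' Two-sided paired Wilcoxon signed-rank test on per-participant values
#' (e.g., maximum interpretability scores of two methods), reported as a
#' continuity-corrected normal-approximation z statistic together with the
#' p-value (exact for n <= 25 without ties). Identical vectors yield z = 0,
#' p = 1 by convention.
#'
#' @param values_a,values_b paired per-participant values, equal length >= 5.
#' @param label optional comparison label.
#' @return An object of class `group_comparison`: list with `z_statistic`,
#'   `p_value`, `n_pairs`, `label`.
#' @export
compare_paired <- function(values_a, values_b, label = "a vs b") {
  if (length(values_a) != length(values_b) || length(values_a) < 5) {
    stopf("values must be paired with length >= 5")
  }
  w <- wilcoxon_signed_rank(values_a - values_b)
  structure(list(z_statistic = w$z, p_value = w$p,
                 n_pairs = length(values_a), label = label),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: z = %.2f, p = %.3g (n = %d)\n",
              x$label, x$z_statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' Interpretability scoring of a feature map against EEG
#'
#' Convenience wrapper binding the per-participant pieces together: computes
#' each participant's correlation time course between the absolute averaged
#' EEG and their feature map, the per-participant maximum score and latency,
#' and the FDR-corrected group significance mask.
#'
#' @param eeg_means channels x samples x participants array of averaged EEG.
#' @param features channels x samples x participants array of nonnegative
#'   feature maps (same participant order).
#' @param times sample latencies, seconds.
#' @param alpha FDR level.
#' @return An object of class `interpretability_result`: list with
#'   `r_timecourses` (participants x samples), `max_scores`, `max_latencies`,
#'   `group_mask`, `p_raw`, `p_adjusted`.
#' @export
interpretability_score <- function(eeg_means, features, times, alpha = 0.05) {
  stopifnot(length(dim(eeg_means)) == 3, all(dim(eeg_means) == dim(features)))
  P <- dim(eeg_means)[3]
  tc <- t(vapply(seq_len(P), function(p) {
    interpretability_timecourse(eeg_means[, , p], features[, , p])
  }, numeric(dim(eeg_means)[2])))
  mx <- lapply(seq_len(P), function(p) max_score_and_latency(tc[p, ], times))
  sig <- if (P >= 5) group_significance(tc, alpha) else {
    list(p_raw = rep(NA_real_, ncol(tc)), p_adjusted = rep(NA_real_, ncol(tc)),
         group_mask = rep(FALSE, ncol(tc)), alpha = alpha)
  }
  structure(list(r_timecourses = tc,
                 max_scores = vapply(mx, `[[`, numeric(1), "max_score"),
                 max_latencies = vapply(mx, `[[`, numeric(1), "max_latency"),
                 group_mask = sig$group_mask, p_raw = sig$p_raw,
                 p_adjusted = sig$p_adjusted, times = times, alpha = alpha),
            class = "interpretability_result")
}

#' @export
print.interpretability_result <- function(x, ...) {
  cat(sprintf(
    "<interpretability_result> %d participants, max score %.3f +/- %.3f, %d/%d significant samples\n",
    nrow(x$r_timecourses), mean(x$max_scores),
    sd(x$max_scores) / sqrt(length(x$max_scores)),
    sum(x$group_mask), length(x$group_mask)))
  invisible(x)
}
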