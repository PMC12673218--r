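#' Participant-wise cross-validation split plan
#'
#' Assigns whole participants to train/validation/test sets for each fold so
#' that no participant's trials ever appear in more than one set of a fold
#' (the leakage guard for between-participant generalization). Set sizes are
#' `round(fraction * N)` for validation and test, with the remainder going to
#' the training set. Test (and validation) memberships rotate across folds.
#'
#' @param participants character vector (or factor) of participant ids.
#' @param n_folds number of folds (default 5).
#' @param fractions length-3 numeric `(train, val, test)` summing to 1;
#'   default `c(0.81, 0.10, 0.09)`.
#' @param seed RNG seed; identical seeds give identical plans.
#' @return An object of class `split_plan`: a list with `folds` (each a list
#'   with `train`, `val`, `test` character vectors) and `n_folds`.
#' @examples
#' plan <- make_participant_splits(sprintf("P%02d", 1:26))
#' lengths(plan$folds[[1]])
#' @export
make_participant_splits <- function(participants, n_folds = 5,
                                    fractions = c(0.81, 0.10, 0.09),
                                    seed = 1L) {
  participants <- unique(as.character(participants))
  n <- length(participants)
  if (n < 3) stopf("need at least 3 participants, got %d", n)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be (train, val, test) summing to 1")
  }
  if (!is_count(n_folds)) stopf("n_folds must be a count")
  n_val <- max(1L, round(fractions[2] * n))
  n_test <- max(1L, round(fractions[3] * n))
  n_train <- n - n_val - n_test
  if (n_train < 1) stopf("split leaves no training participants (N = %d)", n)

  folds <- with_seed(seed, {
    perm <- sample(participants)
    lapply(seq_len(n_folds), function(f) {
      # rotate the permuted roster so held-out sets differ across folds
      shift <- ((f - 1) * (n_val + n_test)) %% n
      roster <- perm[((seq_len(n) - 1 + shift) %% n) + 1]
      list(train = sort(roster[seq_len(n_train)]),
           val = sort(roster[n_train + seq_len(n_val)]),
           test = sort(roster[n_train + n_val + seq_len(n_test)]))
    })
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 participants = participants, fractions = fractions,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  s <- lengths(x$folds[[1]])
  cat(sprintf("<split_plan> %d folds over %d participants (train %d / val %d / test %d)\n",
              x$n_folds, length(x$participants), s[1], s[2], s[3]))
  invisible(x)
}

# stop() unless the three sets of every fold are pairwise disjoint and cover
# all participants
assert_split_plan <- function(plan) {
  for (f in seq_along(plan$folds)) {
    fo <- plan$folds[[f]]
    all_p <- c(fo$train, fo$val, fo$test)
    if (anyDuplicated(all_p)) {
      stopf("fold %d: participant sets overlap", f)
    }
    if (!setequal(all_p, plan$participants)) {
      stopf("fold %d: sets do not cover all participants", f)
    }
  }
  invisible(TRUE)
}
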