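#' Categorical cross-entropy
#'
#' Mean over trials of `-sum_c t_c log f(y)_c`, where `t` is the one-hot true
#' label and `f(y)` the softmax class probabilities. Probabilities of exactly
#' zero at the true class are clamped at the machine epsilon with a warning.
#'
#' @param true_onehot trials x classes 0/1 matrix (one 1 per row).
#' @param predicted_probs trials x classes matrix of nonnegative rows summing
#'   to 1.
#' @return Nonnegative scalar loss.
#' @examples
#' cross_entropy(diag(3), matrix(1 / 3, 3, 3))  # log(3)
#' @export
cross_entropy <- function(true_onehot, predicted_probs) {
  true_onehot <- as.matrix(true_onehot)
  predicted_probs <- as.matrix(predicted_probs)
  if (!all(dim(true_onehot) == dim(predicted_probs))) {
    stopf("true_onehot and predicted_probs must have identical shapes")
  }
  if (any(predicted_probs < 0) ||
      any(abs(rowSums(predicted_probs) - 1) > 1e-6)) {
    stopf("predicted_probs rows must be nonnegative and sum to 1")
  }
  p_true <- rowSums(true_onehot * predicted_probs)
  if (any(p_true == 0)) {
    warnf("probability 0 at the true class; clamping at machine epsilon")
    p_true <- pmax(p_true, .Machine$double.eps)
  }
  mean(-log(p_true))
}

#' Categorical accuracy
#'
#' Exact fraction of predictions matching the labels.
#'
#' @param predictions vector of predicted class identifiers.
#' @param labels vector of true class identifiers, same length.
#' @return Fraction in `[0, 1]`.
#' @export
categorical_accuracy <- function(predictions, labels) {
  if (!length(predictions) || length(predictions) != length(labels)) {
    stopf("predictions and labels must be nonempty and of equal length")
  }
  mean(as.character(predictions) == as.character(labels))
}

# one-hot encode a factor into trials x classes
onehot <- function(labels, class_names) {
  m <- matrix(0, length(labels), length(class_names))
  m[cbind(seq_along(labels), match(as.character(labels), class_names))] <- 1
  colnames(m) <- class_names
  m
}
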