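#' Time-point-wise multinomial logistic-regression baseline
#'
#' Fits one ridge-penalized multinomial logistic model per sample index on
#' the channels-at-that-sample feature vector (the standard time-resolved
#' decoding baseline), and evaluates it on the test set, yielding a decoding
#' accuracy time course and its maximum over time.
#'
#' @param train,test [epochs_set()]s on identical channel/sample grids.
#' @param regularization L2 (weight-decay) penalty passed to the multinomial
#'   fit; keeps degenerate time points (collinear channels) well posed.
#' @return List with `accuracy_timecourse` (one accuracy per sample),
#'   `times`, and `max_accuracy = max(accuracy_timecourse)`.
#' @export
pointwise_logreg_baseline <- function(train, test, regularization = 1.0) {
  stopifnot(inherits(train, "epochs_set"), inherits(test, "epochs_set"))
  if (dim(train$data)[2] != dim(test$data)[2] ||
      dim(train$data)[3] != dim(test$data)[3]) {
    stopf("train and test must share channel and sample grids")
  }
  n_samp <- dim(train$data)[3]
  ytr <- droplevels(train$labels)
  yte <- as.character(test$labels)
  acc <- numeric(n_samp)
  for (s in seq_len(n_samp)) {
    xtr <- train$data[, , s]
    xte <- test$data[, , s]
    df <- data.frame(y = ytr, xtr)
    fit <- nnet::multinom(y ~ ., data = df, decay = regularization,
                          trace = FALSE, maxit = 200)
    pred <- as.character(predict(fit, newdata = data.frame(xte)))
    acc[s] <- mean(pred == yte)
  }
  list(accuracy_timecourse = acc, times = train$times,
       max_accuracy = max(acc))
}
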