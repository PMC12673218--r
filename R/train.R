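#' Training configuration
#'
#' Optimization settings for [train_decoder()]. The per-family defaults
#' follow the study protocol: the EEGNet-style network is trained with
#' stochastic gradient descent (learning rate 1e-4, momentum 0.5,
#' exponential decay 0.94 applied per epoch in a staircase fashion), the
#' residual network with Adam (learning rate 1e-3); both use batch size 64
#' and early stopping after 25 epochs without a decrease in validation loss.
#'
#' @param optimizer `"sgd_momentum"` or `"adam"`.
#' @param learning_rate positive step size.
#' @param momentum momentum fraction (sgd_momentum).
#' @param lr_decay_factor per-epoch exponential decay factor (1 = none).
#' @param decay_staircase logical; if `TRUE` the decay is applied once per
#'   epoch, otherwise continuously per step.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of training epochs.
#' @param early_stop_patience epochs without validation-loss decrease before
#'   stopping.
#' @param seed RNG seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("sgd_momentum", "adam"),
                         learning_rate = 1e-4, momentum = 0.5,
                         lr_decay_factor = 0.94, decay_staircase = TRUE,
                         batch_size = 64L, max_epochs = 500L,
                         early_stop_patience = 25L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (!is_number(learning_rate) || learning_rate <= 0) {
    stopf("learning_rate must be > 0")
  }
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  if (!is_count(early_stop_patience)) stopf("early_stop_patience must be >= 1")
  if (!is_count(max_epochs)) stopf("max_epochs must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, lr_decay_factor = lr_decay_factor,
                 decay_staircase = decay_staircase,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Study-default training configuration for a decoder family
#'
#' @param family `"eegnet_style"` or `"residual_small"`.
#' @param ... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
default_train_config <- function(family, ...) {
  base <- if (family == "residual_small") {
    list(optimizer = "adam", learning_rate = 1e-3, lr_decay_factor = 1)
  } else {
    list(optimizer = "sgd_momentum", learning_rate = 1e-4, momentum = 0.5,
         lr_decay_factor = 0.94)
  }
  args <- modifyList(base, list(...))
  do.call(train_config, args)
}

opt_init <- function(params, cfg) {
  zeros <- lapply(params, function(p) p * 0)  # keep each parameter's shape
  if (cfg$optimizer == "adam") {
    list(m = zeros, v = zeros, t = 0L)
  } else {
    list(v = zeros)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opt_step <- function(params, grads, state, cfg, lr) {
  if (cfg$optimizer == "sgd_momentum") {
    for (nm in names(params)) {
      state$v[[nm]] <- cfg$momentum * state$v[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + state$v[[nm]]
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    for (nm in names(params)) {
      g <- grads[[nm]]
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# forward in evaluation mode, batched to bound memory; returns (ncls, N) probs
predict_probs <- function(dec, X, batch = 256L) {
  N <- dim(X)[3]
  out <- matrix(0, dec$n_classes, N)
  for (s in seq(1, N, by = batch)) {
    idx <- s:min(s + batch - 1L, N)
    out[, idx] <- decoder_forward(dec, X[, , idx, drop = FALSE])$probs
  }
  out
}

#' Train a decoder
#'
#' Minimizes categorical cross-entropy by minibatch backpropagation under
#' the given [train_config()]. Training stops at `max_epochs` or once the
#' validation loss has not decreased for `early_stop_patience` consecutive
#' epochs; the returned decoder carries the weights of the best-validation
#' epoch and the full per-epoch history. Train and validation sets must not
#' share participants (leakage guard).
#'
#' @param decoder an untrained [build_decoder()] output.
#' @param train,val [epochs_set()]s with identical channel/sample grids and
#'   class sets, disjoint participants.
#' @param cfg a [train_config()].
#' @param fold_id optional fold index stored on the result.
#' @param verbose print per-epoch progress.
#' @return The decoder with added elements `history` (data.frame: epoch,
#'   train_loss, val_loss, train_acc, val_acc), `best_epoch`, `fold_id`,
#'   and class `trained_decoder`.
#' @export
train_decoder <- function(decoder, train, val, cfg = NULL, fold_id = NA_integer_,
                          verbose = FALSE) {
  stopifnot(inherits(decoder, "eeg_decoder"),
            inherits(train, "epochs_set"), inherits(val, "epochs_set"))
  if (is.null(cfg)) cfg <- default_train_config(decoder$spec$family)
  if (dim(train$data)[2] != dim(val$data)[2] ||
      dim(train$data)[3] != dim(val$data)[3]) {
    stopf("train and val must share channel and sample grids")
  }
  overlap <- intersect(unique(as.character(train$participants)),
                       unique(as.character(val$participants)))
  if (length(overlap)) {
    stopf("participant leakage between train and val: %s",
          paste(overlap, collapse = ", "))
  }
  cls <- decoder$class_names
  if (!all(levels(train$labels) %in% cls)) {
    stopf("training labels outside the decoder's class set")
  }

  Xtr <- epochs_input(train)
  # fixed input normalization (a non-trainable scaling layer): bring the
  # training data to unit sd so the seeded initialization is well scaled;
  # stored on the decoder and chain-ruled through saliency
  s_tr <- sd(Xtr)
  decoder$input_scale <- if (s_tr > 0) 1 / s_tr else 1
  ytr <- onehot(train$labels, cls)
  Xval <- epochs_input(val)
  yval <- onehot(val$labels, cls)
  Ntr <- dim(Xtr)[3]
  nb <- cfg$batch_size

  params <- decoder$params
  state <- opt_init(params, cfg)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), train_acc = numeric(),
                        val_acc = numeric())
  best_loss <- Inf; best_epoch <- 0L; best_params <- params
  stall <- 0L
  n_steps <- ceiling(Ntr / nb)

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- if (cfg$decay_staircase) {
        cfg$learning_rate * cfg$lr_decay_factor^(epoch - 1)
      } else cfg$learning_rate
      perm <- sample.int(Ntr)
      tr_loss <- 0; tr_correct <- 0
      for (s in seq_len(n_steps)) {
        idx <- perm[((s - 1) * nb + 1):min(s * nb, Ntr)]
        if (!cfg$decay_staircase) {
          lr <- cfg$learning_rate *
            cfg$lr_decay_factor^((epoch - 1) + (s - 1) / n_steps)
        }
        dec_tmp <- decoder; dec_tmp$params <- params
        fw <- decoder_forward(dec_tmp, Xtr[, , idx, drop = FALSE],
                              training = TRUE)
        yb <- t(ytr[idx, , drop = FALSE])          # (ncls, nbatch)
        p_true <- colSums(yb * fw$probs)
        loss <- mean(-log(pmax(p_true, .Machine$double.eps)))
        if (!is.finite(loss)) {
          stopf("NaN/Inf loss at epoch %d step %d (lr %.3g)", epoch, s, lr)
        }
        tr_loss <- tr_loss + loss * length(idx)
        tr_correct <- tr_correct +
          sum(apply(fw$probs, 2, which.max) == apply(yb, 2, which.max))
        dlogits <- (fw$probs - yb) / length(idx)
        bw <- decoder_backward(dec_tmp, fw$cache, dlogits)
        upd <- opt_step(params, bw$grads, state, cfg, lr)
        params <- upd$params; state <- upd$state
      }
      dec_tmp <- decoder; dec_tmp$params <- params
      pv <- predict_probs(dec_tmp, Xval)
      val_loss <- cross_entropy(yval, t(pv))
      val_acc <- mean(apply(pv, 2, which.max) ==
                        apply(yval, 1, which.max))
      history[epoch, ] <- list(epoch, tr_loss / Ntr, val_loss,
                               tr_correct / Ntr, val_acc)
      msgf(verbose, "epoch %3d  train %.4f  val %.4f  acc %.3f/%.3f",
           epoch, tr_loss / Ntr, val_loss, tr_correct / Ntr, val_acc)
      if (val_loss < best_loss) {
        best_loss <- val_loss; best_epoch <- epoch
        best_params <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
  })

  decoder$params <- best_params
  decoder$history <- history
  decoder$best_epoch <- best_epoch
  decoder$fold_id <- fold_id
  decoder$train_participants <- unique(as.character(train$participants))
  decoder$val_participants <- unique(as.character(val$participants))
  decoder$train_config <- cfg
  class(decoder) <- c("trained_decoder", class(decoder))
  decoder
}

#' Evaluate a trained decoder
#'
#' Computes test-set predictions and categorical accuracy, retaining
#' per-trial correctness for correct-trial attribution filtering.
#'
#' @param trained a [train_decoder()] result.
#' @param test an [epochs_set()]; its classes must be known to the decoder.
#' @param check_leakage reject test sets sharing participants with the
#'   decoder's train/validation sets (default `TRUE`; disable when
#'   deliberately feeding back all participants for feature extraction).
#' @return An object of class `evaluation_result`: list with `accuracy`,
#'   `per_trial_predictions` (factor), `per_trial_correct` (logical),
#'   `labels`, `participants`.
#' @export
evaluate_decoder <- function(trained, test, check_leakage = TRUE) {
  stopifnot(inherits(trained, "eeg_decoder"), inherits(test, "epochs_set"))
  unknown <- setdiff(levels(droplevels(test$labels)), trained$class_names)
  if (length(unknown)) {
    stopf("test contains class(es) unknown to the decoder: %s",
          paste(unknown, collapse = ", "))
  }
  if (check_leakage && !is.null(trained$train_participants)) {
    overlap <- intersect(unique(as.character(test$participants)),
                         c(trained$train_participants,
                           trained$val_participants))
    if (length(overlap)) {
      stopf("participant leakage into the test set: %s",
            paste(overlap, collapse = ", "))
    }
  }
  probs <- predict_probs(trained, epochs_input(test))
  pred <- factor(trained$class_names[apply(probs, 2, which.max)],
                 levels = trained$class_names)
  correct <- as.character(pred) == as.character(test$labels)
  structure(list(accuracy = categorical_accuracy(pred, test$labels),
                 per_trial_predictions = pred,
                 per_trial_correct = correct,
                 labels = test$labels,
                 participants = test$participants),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> accuracy %.3f over %d trials\n",
              x$accuracy, length(x$per_trial_correct)))
  invisible(x)
}
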