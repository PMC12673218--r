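#' Permute trial labels
#'
#' Randomly permutes the per-trial class labels of an epochs set (the
#' empirical-chance-level control: decoders trained on permuted labels must
#' score at 1/n_classes on held-out participants).
#'
#' @param epochs an [epochs_set()].
#' @param seed permutation seed.
#' @return The epochs set with permuted labels.
#' @export
permute_labels <- function(epochs, seed = 1L) {
  stopifnot(inherits(epochs, "epochs_set"))
  perm <- with_seed(seed, sample.int(length(epochs$labels)))
  epochs$labels <- epochs$labels[perm]
  epochs
}

#' Participant-wise cross-validated decoding
#'
#' Trains one decoder per fold of a participant-wise split plan and
#' evaluates each on its held-out test participants.
#'
#' @param epochs an [epochs_set()].
#' @param spec an [architecture_spec()].
#' @param plan a [make_participant_splits()] plan.
#' @param cfg a [train_config()] (default: the family's study defaults).
#' @param seed base seed; fold f trains with seed `seed + 101 * f`.
#' @param verbose print progress.
#' @return List with `decoders` (one trained decoder per fold),
#'   `evaluations`, `accuracies`, and `mean_accuracy`.
#' @export
run_cv <- function(epochs, spec, plan, cfg = NULL, seed = 1L,
                   verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  assert_split_plan(plan)
  decoders <- vector("list", plan$n_folds)
  evals <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    fo <- plan$folds[[f]]
    msgf(verbose, "[fold %d/%d] train %d / val %d / test %d participants",
         f, plan$n_folds, length(fo$train), length(fo$val), length(fo$test))
    fold_seed <- seed + 101L * f
    fcfg <- cfg %||% default_train_config(spec$family)
    fcfg$seed <- fold_seed
    dec <- build_decoder(spec, dim(epochs$data)[2], dim(epochs$data)[3],
                         nlevels(epochs$labels), levels(epochs$labels),
                         seed = fold_seed)
    trained <- train_decoder(dec,
                             subset_participants(epochs, fo$train),
                             subset_participants(epochs, fo$val),
                             fcfg, fold_id = f, verbose = verbose)
    evals[[f]] <- evaluate_decoder(trained,
                                   subset_participants(epochs, fo$test))
    msgf(verbose, "[fold %d] test accuracy %.3f (%d epochs)",
         f, evals[[f]]$accuracy, nrow(trained$history))
    decoders[[f]] <- trained
  }
  acc <- vapply(evals, `[[`, numeric(1), "accuracy")
  list(decoders = decoders, evaluations = evals, accuracies = acc,
       mean_accuracy = mean(acc))
}

# per-fold feature extraction: correct trials of the chosen participant pool
# for every (method, layer preset, condition); also the matching
# per-participant EEG means over the same correct trials
extract_fold_features <- function(trained, epochs, methods, layer_presets_v,
                                  all_participants = TRUE, fold_id = 1L) {
  pool <- if (all_participants) epochs else {
    subset_participants(epochs,
                        setdiff(levels(epochs$participants),
                                c(trained$train_participants,
                                  trained$val_participants)))
  }
  ev <- evaluate_decoder(trained, pool, check_leakage = FALSE)
  correct <- select_correct_trials(ev)
  if (!length(correct)) {
    warnf("fold %d: no correctly predicted trials; skipping", fold_id)
    return(NULL)
  }
  conds <- levels(pool$labels)
  maps <- list()
  for (method in methods) {
    layers <- if (method == "saliency") "input" else layer_presets_v
    for (layer in layers) {
      key <- if (method == "saliency") "saliency" else paste0("gradcam_", layer)
      real_layer <- if (method == "saliency") NULL else layer
      tl <- attribute_trials(trained, pool, trials = correct,
                             method = method, layer = real_layer)
      for (i in seq_along(tl)) tl[[i]]$fold <- fold_id
      for (cond in conds) {
        sel <- vapply(tl, function(m) m$target_class == cond, logical(1))
        maps[[key]][[cond]] <- c(maps[[key]][[cond]] %||% list(), tl[sel])
      }
    }
  }
  # EEG operand: per participant x condition mean over the same correct trials
  eeg_means <- list()
  for (cond in conds) {
    for (p in levels(pool$participants)) {
      ids <- correct[as.character(pool$labels[correct]) == cond &
                       as.character(pool$participants[correct]) == p]
      if (!length(ids)) next
      m <- apply(pool$data[ids, , , drop = FALSE], c(2, 3), mean)
      eeg_means[[cond]][[p]] <- list(sum = m, n = 1L)
    }
  }
  list(maps = maps, eeg_means = eeg_means)
}

# merge per-fold EEG-mean lists: average the per-fold participant means
merge_eeg_means <- function(fold_list) {
  out <- list()
  for (fl in fold_list) {
    if (is.null(fl)) next
    for (cond in names(fl$eeg_means)) {
      for (p in names(fl$eeg_means[[cond]])) {
        cur <- out[[cond]][[p]]
        add <- fl$eeg_means[[cond]][[p]]
        out[[cond]][[p]] <- if (is.null(cur)) add else {
          list(sum = cur$sum + add$sum, n = cur$n + add$n)
        }
      }
    }
  }
  lapply(out, function(cnd) lapply(cnd, function(x) x$sum / x$n))
}

#' Run the full interpretability-assessment pipeline
#'
#' End to end: simulate the configured dataset, build the participant-wise
#' split plan, train and evaluate each decoder family per fold, extract
#' attributions from correctly predicted trials, aggregate them
#' (trials, then participants, then folds, per condition), score
#' interpretability against the absolute averaged EEG, run the group-level
#' Wilcoxon/FDR statistics and the pairwise comparisons between methods,
#' layers, and networks, and compute ground-truth-recovery metrics against
#' the planted components.
#'
#' @param cfg a [run_config()] (or the path of a YAML file for
#'   [load_config()]).
#' @return An object of class `pipeline_report`; see [write_report()] for
#'   serialization. Key elements: `accuracy` (per network/fold),
#'   `interpretability` (per network/method-layer score summaries and
#'   per-participant maxima), `comparisons` (pairwise z/p), `recovery`
#'   (latency error and top-channel overlap per signal class), `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  epochs <- simulate_dataset(cfg$sim)
  plan <- make_participant_splits(levels(epochs$participants),
                                  n_folds = cfg$n_folds,
                                  fractions = cfg$fractions,
                                  seed = cfg$seed)
  tcfg_of <- function(family) {
    tc <- default_train_config(family, max_epochs = cfg$max_epochs,
                               batch_size = cfg$batch_size,
                               early_stop_patience = cfg$early_stop_patience)
    if (family %in% names(cfg$learning_rates)) {
      tc$learning_rate <- unname(cfg$learning_rates[family])
    }
    tc
  }
  networks <- list()
  acc_rows <- list()
  for (family in cfg$decoders) {
    msgf(cfg$verbose, "[%s] training %d folds", family, cfg$n_folds)
    spec <- architecture_spec(family)
    cv <- run_cv(epochs, spec, plan, tcfg_of(family), seed = cfg$seed,
                 verbose = cfg$verbose)
    presets <- layer_presets(spec)
    fold_feats <- lapply(seq_len(plan$n_folds), function(f) {
      msgf(cfg$verbose, "[%s] attribution, fold %d", family, f)
      extract_fold_features(cv$decoders[[f]], epochs, cfg$methods,
                            unname(presets[cfg$layers]),
                            cfg$attribute_all_participants, fold_id = f)
    })
    eeg_means <- merge_eeg_means(fold_feats)
    # pool trial maps across folds per (method-layer key, condition)
    keys <- unique(unlist(lapply(fold_feats, function(fl) names(fl$maps))))
    aggregates <- list()
    scores <- list()
    for (key in keys) {
      per_cond <- list()
      for (cond in levels(epochs$labels)) {
        trial_maps <- unlist(lapply(fold_feats, function(fl) {
          fl$maps[[key]][[cond]]
        }), recursive = FALSE)
        if (!length(trial_maps)) next
        per_cond[[cond]] <- aggregate_maps(trial_maps)
      }
      aggregates[[key]] <- per_cond
      # per-participant interpretability, averaged over conditions
      pps <- levels(epochs$participants)
      tc_sum <- NULL; tc_n <- NULL
      for (cond in names(per_cond)) {
        ag <- per_cond[[cond]]
        for (j in seq_along(ag$participants)) {
          p <- ag$participants[j]
          em <- eeg_means[[cond]][[p]]
          if (is.null(em)) next
          r <- interpretability_timecourse(em, ag$per_participant[, , j])
          if (is.null(tc_sum)) {
            tc_sum <- matrix(0, length(pps), length(r),
                             dimnames = list(pps, NULL))
            tc_n <- matrix(0, length(pps), length(r),
                           dimnames = list(pps, NULL))
          }
          pi <- match(p, pps)
          add <- ifelse(is.na(r), 0, r)
          tc_sum[pi, ] <- tc_sum[pi, ] + add
          tc_n[pi, ] <- tc_n[pi, ] + !is.na(r)
        }
      }
      if (is.null(tc_sum)) next
      tc <- tc_sum / ifelse(tc_n == 0, NA, tc_n)
      tc <- tc[rowSums(tc_n) > 0, , drop = FALSE]
      # channel-uniform feature maps (e.g. Grad-CAM from layers without a
      # channel extent) have no defined correlation anywhere; record nothing
      if (nrow(tc) == 0) next
      mx <- lapply(seq_len(nrow(tc)), function(i) {
        max_score_and_latency(tc[i, ], epochs$times)
      })
      sig <- if (nrow(tc) >= 5) group_significance(tc, cfg$alpha) else {
        list(group_mask = rep(FALSE, ncol(tc)),
             p_raw = rep(NA_real_, ncol(tc)),
             p_adjusted = rep(NA_real_, ncol(tc)))
      }
      scores[[key]] <- list(
        participants = rownames(tc),
        r_timecourses = tc,
        max_scores = vapply(mx, `[[`, numeric(1), "max_score"),
        max_latencies = vapply(mx, `[[`, numeric(1), "max_latency"),
        group_mask = sig$group_mask, p_raw = sig$p_raw,
        p_adjusted = sig$p_adjusted)
    }
    networks[[family]] <- list(cv = cv, aggregates = aggregates,
                               scores = scores, presets = presets)
    acc_rows[[family]] <- data.frame(
      network = family, fold = seq_len(plan$n_folds),
      accuracy = cv$accuracies)
  }

  logreg <- NULL
  if (cfg$include_logreg) {
    msgf(cfg$verbose, "[logreg] time-point-wise baseline")
    curves <- lapply(plan$folds, function(fo) {
      pointwise_logreg_baseline(
        subset_participants(epochs, c(fo$train, fo$val)),
        subset_participants(epochs, fo$test))
    })
    mean_curve <- rowMeans(vapply(curves, `[[`,
                                  numeric(length(epochs$times)),
                                  "accuracy_timecourse"))
    logreg <- list(mean_curve = mean_curve, times = epochs$times,
                   max_accuracy = max(mean_curve))
  }

  # pairwise comparisons of per-participant max scores (Table-2-style)
  comparisons <- list()
  for (family in names(networks)) {
    sc <- networks[[family]]$scores
    kk <- names(sc)
    if (length(kk) >= 2) {
      for (i in seq_len(length(kk) - 1)) {
        for (j in (i + 1):length(kk)) {
          common <- intersect(sc[[kk[i]]]$participants,
                              sc[[kk[j]]]$participants)
          if (length(common) < 5) next
          a <- sc[[kk[i]]]$max_scores[match(common, sc[[kk[i]]]$participants)]
          b <- sc[[kk[j]]]$max_scores[match(common, sc[[kk[j]]]$participants)]
          comparisons[[length(comparisons) + 1L]] <-
            compare_paired(a, b, sprintf("%s: %s vs %s", family, kk[i], kk[j]))
        }
      }
    }
  }
  if (all(c("eegnet_style", "residual_small") %in% names(networks))) {
    key <- "gradcam_conv1"
    a <- networks$eegnet_style$scores[[key]]
    b <- networks$residual_small$scores[[key]]
    if (!is.null(a) && !is.null(b)) {
      common <- intersect(a$participants, b$participants)
      if (length(common) >= 5) {
        comparisons[[length(comparisons) + 1L]] <- compare_paired(
          a$max_scores[match(common, a$participants)],
          b$max_scores[match(common, b$participants)],
          "eegnet_style vs residual_small (gradcam early)")
      }
    }
  }

  recovery <- ground_truth_recovery(cfg$sim, networks, epochs$times,
                                    epochs$montage, cfg$laplacian)

  report <- structure(list(
    config = config_echo(cfg),
    accuracy = do.call(rbind, acc_rows),
    networks = networks,
    logreg = logreg,
    comparisons = comparisons,
    recovery = recovery,
    times = epochs$times,
    channels = epochs$montage$channel_labels,
    montage = epochs$montage),
    class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# latency error and top-5 channel overlap of each aggregate map against the
# planted component mask of each signal class. The channel profile is read
# from the surface-Laplacian (CSD) transform of the aggregate map at the
# recovered peak latency, the way the study renders topographies.
ground_truth_recovery <- function(sim, networks, times, mont,
                                  lap = laplacian_params()) {
  rows <- list()
  for (cond in sim$class_names) {
    mask <- ground_truth_mask(sim, cond)
    if (!any(mask > 0)) next
    mask_channels <- which(rowSums(mask) > 0)
    peak_t <- times[which.max(colSums(mask))]
    # use the component's stated peak when available
    for (comp in sim$components) {
      if (cond %in% comp$class_selector) peak_t <- comp$peak_latency
    }
    for (family in names(networks)) {
      ags <- networks[[family]]$aggregates
      for (key in names(ags)) {
        ag <- ags[[key]][[cond]]
        if (is.null(ag)) next
        v <- ag$aggregate$values
        tmarg <- colMeans(v)
        pk <- which.max(tmarg)
        win <- max(1, pk - 2):min(length(times), pk + 2)
        csd <- surface_laplacian(v[, win, drop = FALSE], mont, lap)
        top5 <- order(rowMeans(csd), decreasing = TRUE)[1:5]
        rows[[length(rows) + 1L]] <- data.frame(
          network = family, map = key, condition = cond,
          plant_latency = peak_t,
          argmax_latency = times[which.max(tmarg)],
          latency_error = abs(times[which.max(tmarg)] - peak_t),
          top5_overlap = length(intersect(top5, mask_channels)))
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("decoding accuracy (per fold):\n")
  print(x$accuracy, row.names = FALSE)
  for (family in names(x$networks)) {
    sc <- x$networks[[family]]$scores
    for (key in names(sc)) {
      cat(sprintf("  %s %-16s max score %.3f +/- %.3f, %d significant samples\n",
                  family, key, mean(sc[[key]]$max_scores),
                  sd(sc[[key]]$max_scores) / sqrt(length(sc[[key]]$max_scores)),
                  sum(sc[[key]]$group_mask)))
    }
  }
  if (!is.null(x$recovery)) {
    cat("ground-truth recovery:\n")
    print(x$recovery[, c("network", "map", "condition", "latency_error",
                         "top5_overlap")], row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `results.json` (scores, statistics, masks, recovery metrics, and
#' the effective configuration), `accuracy.csv`, `max_scores.csv`, and
#' `comparisons.csv` into `dir`. Two runs with the same configuration and
#' seed produce byte-identical `results.json`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scores <- list()
  for (family in names(report$networks)) {
    sc <- report$networks[[family]]$scores
    scores[[family]] <- lapply(sc, function(s) {
      list(participants = s$participants,
           max_scores = round(s$max_scores, 10),
           max_latencies = round(s$max_latencies, 10),
           mean_max_score = round(mean(s$max_scores), 10),
           n_significant_samples = sum(s$group_mask),
           group_mask = as.integer(s$group_mask))
    })
  }
  comp <- lapply(report$comparisons, function(cmp) {
    list(label = cmp$label, z = round(cmp$z_statistic, 10),
         p = round(cmp$p_value, 12), n = cmp$n_pairs)
  })
  rec <- if (is.null(report$recovery)) NULL else {
    lapply(seq_len(nrow(report$recovery)), function(i) {
      as.list(report$recovery[i, ])
    })
  }
  res <- list(config = report$config,
              accuracy = list(
                per_fold = lapply(seq_len(nrow(report$accuracy)), function(i) {
                  as.list(report$accuracy[i, ])
                }),
                mean_by_network = lapply(
                  split(report$accuracy$accuracy, report$accuracy$network),
                  function(a) round(mean(a), 10))),
              logreg_max_accuracy = if (is.null(report$logreg)) NULL else {
                round(report$logreg$max_accuracy, 10)
              },
              interpretability = scores,
              comparisons = comp,
              recovery = rec)
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write.csv(report$accuracy, file.path(dir, "accuracy.csv"),
            row.names = FALSE)
  mx <- list()
  for (family in names(report$networks)) {
    sc <- report$networks[[family]]$scores
    for (key in names(sc)) {
      mx[[length(mx) + 1L]] <- data.frame(
        network = family, map = key,
        participant = sc[[key]]$participants,
        max_score = sc[[key]]$max_scores,
        max_latency = sc[[key]]$max_latencies)
    }
  }
  if (length(mx)) {
    write.csv(do.call(rbind, mx), file.path(dir, "max_scores.csv"),
              row.names = FALSE)
  }
  if (length(report$comparisons)) {
    write.csv(data.frame(
      label = vapply(report$comparisons, `[[`, character(1), "label"),
      z = vapply(report$comparisons, `[[`, numeric(1), "z_statistic"),
      p = vapply(report$comparisons, `[[`, numeric(1), "p_value"),
      n = vapply(report$comparisons, `[[`, integer(1), "n_pairs")),
      file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  invisible(dir)
}
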