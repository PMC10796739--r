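#' Leave-one-subject-out split plans
#'
#' One plan per subject held out as the test subject. From the remaining
#' subjects, `ceiling(0.1 * (n - 1))` (at least 1) are drawn without
#' replacement as the validation set; the rest train the model. The three
#' sets partition the cohort in every plan.
#'
#' @param subject_ids Character vector of distinct subject ids (>= 3).
#' @param seed Integer seed for the validation draws.
#' @param val_frac Fraction of non-test subjects held out for validation.
#' @return A tibble with `test_subject` and list-columns
#'   `validation_subjects`, `train_subjects`.
#' @export
loso_splits <- function(subject_ids, seed = 1, val_frac = 0.1) {
  ids <- unique(subject_ids)
  if (length(ids) < 3) abort("loso_splits needs at least 3 subjects.")
  .with_seed(seed, {
    plans <- map(ids, function(test_id) {
      rest <- setdiff(ids, test_id)
      n_val <- max(1L, as.integer(ceiling(val_frac * length(rest))))
      val <- sample(rest, n_val)
      list(test_subject = test_id, validation_subjects = val,
           train_subjects = setdiff(rest, val))
    })
    tibble(
      test_subject = map_chr(plans, "test_subject"),
      validation_subjects = map(plans, "validation_subjects"),
      train_subjects = map(plans, "train_subjects")
    )
  })
}

#' Detection metrics for one evaluation split
#'
#' AUC is the rank-statistic (Mann-Whitney) estimate with ties averaged;
#' sensitivity, specificity and F1 come from thresholded predictions
#' (`score >= threshold`), and balanced accuracy is the mean of sensitivity
#' and specificity.
#'
#' @param y_true Logical labels.
#' @param scores Numeric scores.
#' @param threshold Operating threshold.
#' @return A one-row tibble `auc, balanced_accuracy, sensitivity,
#'   specificity, f1`. With a single-class `y_true` the AUC is undefined and
#'   returned as `NA` with a warning.
#' @export
compute_metrics <- function(y_true, scores, threshold) {
  y <- as.logical(y_true)
  auc <- if (all(y) || !any(y)) {
    warn("AUC undefined for single-class y_true; returning NA.")
    NA_real_
  } else {
    r <- rank(scores)
    np <- sum(y)
    (sum(r[y]) - np * (np + 1) / 2) / (np * (length(y) - np))
  }
  pred <- scores >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble(
    auc = auc,
    balanced_accuracy = mean(c(sens, spec)),
    sensitivity = sens,
    specificity = spec,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  )
}

#' Per-task detection accuracy table
#'
#' Plain accuracy of thresholded predictions within each
#' (group, side role, task context) cell, mirroring the per-task breakdown
#' used to inspect where a detector succeeds (e.g. passive tasks in controls
#' versus bimanual tasks in stroke survivors). Cells with no windows are
#' omitted.
#'
#' @param predictions A tibble with columns `group`, `side_role`,
#'   `task_context`, `gdm_label` and `pred`.
#' @return A tibble `group, side_role, task_context, n, accuracy`.
#' @export
per_task_accuracy <- function(predictions) {
  predictions %>%
    group_by(.data$group, .data$side_role, .data$task_context) %>%
    summarise(n = n(), accuracy = mean(.data$pred == .data$gdm_label),
              .groups = "drop")
}

#' Leave-one-subject-out evaluation of the GDM detector
#'
#' For every split: the per-channel normalizer is fitted on the training
#' subjects only and applied to all windows, 28-feature descriptors are
#' recomputed from the normalized windows, the gbt detector is trained with
#' class weights and validation early stopping, the threshold is chosen on
#' validation scores, and metrics are computed on the held-out subject. A
#' test subject with a single class yields threshold-based metrics with AUC
#' `NA` (and a warning).
#'
#' @param windows A cohort windows tibble from [make_cohort_windows()].
#' @param seed Integer seed (validation draws and gbt training).
#' @param fs Sampling rate in Hz.
#' @param val_frac Validation fraction of non-test subjects.
#' @param params Optional gbt parameter overrides (see [train_detector()]).
#' @return An object of class `gdm_loso`: per-split metrics, their unweighted
#'   means, pooled held-out predictions, and the per-task accuracy table.
#' @export
run_loso <- function(windows, seed = 1, fs = 25, val_frac = 0.1,
                     params = NULL) {
  ids <- unique(windows$subject_id)
  splits <- loso_splits(ids, seed = seed, val_frac = val_frac)
  p <- utils::modifyList(.default_gbt_params(), params %||% list())
  mats_raw <- .window_channel_mats(windows)
  y <- windows$gdm_label
  metric_rows <- vector("list", nrow(splits))
  pred_rows <- vector("list", nrow(splits))
  for (k in seq_len(nrow(splits))) {
    idx_te <- windows$subject_id == splits$test_subject[k]
    idx_val <- windows$subject_id %in% splits$validation_subjects[[k]]
    idx_tr <- windows$subject_id %in% splits$train_subjects[[k]]
    mu <- map_dbl(mats_raw, function(m) mean(m[, idx_tr]))
    sdv <- map_dbl(mats_raw, function(m) sd(as.numeric(m[, idx_tr])))
    if (any(sdv == 0)) abort("Zero-variance channel in a training split.")
    mats <- map2(mats_raw, seq_along(mats_raw),
                 function(m, ch) (m - mu[ch]) / sdv[ch])
    x <- .features_from_mats(mats, fs)
    weights <- compute_class_weights(y[idx_tr])
    booster <- .train_gbt(x[idx_tr, , drop = FALSE], y[idx_tr],
                          x[idx_val, , drop = FALSE], y[idx_val],
                          weights, seed, p)
    val_scores <- predict(booster, xgboost::xgb.DMatrix(
      x[idx_val, , drop = FALSE]))
    threshold <- select_threshold(val_scores, y[idx_val])
    te_scores <- predict(booster, xgboost::xgb.DMatrix(
      x[idx_te, , drop = FALSE]))
    m <- if (all(y[idx_te]) || !any(y[idx_te])) {
      warn(sprintf("Test subject %s has a single class; AUC omitted.",
                   splits$test_subject[k]))
      suppressWarnings(compute_metrics(y[idx_te], te_scores, threshold))
    } else {
      compute_metrics(y[idx_te], te_scores, threshold)
    }
    metric_rows[[k]] <- bind_cols(
      tibble(test_subject = splits$test_subject[k], threshold = threshold), m)
    pred_rows[[k]] <- windows[idx_te, c("subject_id", "group", "side",
                                        "side_role", "start_index",
                                        "task_context", "gdm_label")] %>%
      mutate(score = te_scores, pred = classify(te_scores, threshold))
  }
  split_metrics <- bind_rows(metric_rows)
  predictions <- bind_rows(pred_rows)
  mean_metrics <- split_metrics %>%
    summarise(auc = mean(.data$auc, na.rm = TRUE),
              balanced_accuracy = mean(.data$balanced_accuracy),
              sensitivity = mean(.data$sensitivity),
              specificity = mean(.data$specificity),
              f1 = mean(.data$f1))
  structure(
    list(splits = splits, split_metrics = split_metrics,
         mean_metrics = mean_metrics, predictions = predictions,
         per_task = per_task_accuracy(predictions),
         seed = seed, fs = fs),
    class = "gdm_loso"
  )
}
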