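#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one place; each default
#' is the value used throughout the analysis (0.1-12 Hz 4th-order
#' Butterworth, 25 Hz, 3 s windows with 70% overlap, one-third GDM labelling
#' rule, 10% validation hold-out, gbt backend).
#'
#' @param n_stroke,n_control Cohort sizes.
#' @param fs_raw Raw simulation rate in Hz.
#' @param fs Working rate after downsampling in Hz.
#' @param low_hz,high_hz,order Band-pass specification.
#' @param win_s,overlap,gdm_fraction Windowing parameters.
#' @param val_frac Validation fraction of non-test subjects.
#' @param backend Detector backend.
#' @param mask_rule Sample-mask rule (`"majority"` or `"any"`).
#' @param seed Master seed; all stage seeds derive from it.
#' @param gbt_params Optional detector parameter overrides.
#' @param out_dir Optional output directory for reports.
#' @return A list of class `gdm_config`.
#' @export
gdm_config <- function(n_stroke = 20, n_control = 10, fs_raw = 100, fs = 25,
                       low_hz = 0.1, high_hz = 12, order = 4, win_s = 3,
                       overlap = 0.7, gdm_fraction = 1 / 3, val_frac = 0.1,
                       backend = "gbt", mask_rule = "majority", seed = 1,
                       gbt_params = NULL, out_dir = NULL) {
  structure(
    list(n_stroke = n_stroke, n_control = n_control, fs_raw = fs_raw,
         fs = fs, low_hz = low_hz, high_hz = high_hz, order = order,
         win_s = win_s, overlap = overlap, gdm_fraction = gdm_fraction,
         val_frac = val_frac, backend = backend, mask_rule = mask_rule,
         seed = seed, gbt_params = gbt_params, out_dir = out_dir),
    class = "gdm_config"
  )
}

#' Validate a pipeline configuration
#'
#' @param config A [gdm_config()].
#' @return A character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  p <- character()
  if (!(config$low_hz > 0 && config$low_hz < config$high_hz)) {
    p <- c(p, "Filter edges must satisfy 0 < low_hz < high_hz.")
  }
  if (config$fs <= 2 * config$high_hz) {
    p <- c(p, sprintf("Nyquist violation: high_hz %g requires fs > %g.",
                      config$high_hz, 2 * config$high_hz))
  }
  if (config$fs_raw < 2 * config$fs ||
      abs(config$fs_raw / config$fs - round(config$fs_raw / config$fs)) > 1e-9) {
    p <- c(p, "fs_raw must be an integer multiple of fs (and at least 2x).")
  }
  if (config$overlap < 0 || config$overlap >= 1) {
    p <- c(p, "overlap must be in [0, 1).")
  } else if (floor(config$win_s * config$fs * (1 - config$overlap)) < 1) {
    p <- c(p, "overlap leaves a zero-sample hop.")
  }
  if (floor(config$win_s * config$fs) < 2) {
    p <- c(p, "win_s * fs must cover at least 2 samples.")
  }
  if (config$gdm_fraction <= 0 || config$gdm_fraction > 1) {
    p <- c(p, "gdm_fraction must be in (0, 1].")
  }
  if (config$val_frac <= 0 || config$val_frac >= 1) {
    p <- c(p, "val_frac must be in (0, 1).")
  }
  if (config$n_stroke + config$n_control < 3) {
    p <- c(p, "Need at least 3 subjects for leave-one-subject-out.")
  }
  if (config$backend != "gbt") {
    p <- c(p, sprintf("Unknown backend '%s'.", config$backend))
  }
  p
}

#' Score every window of a cohort with one pooled detector
#'
#' Trains a single detector on a subject-wise split (a seeded validation
#' hold-out of subjects for early stopping and threshold selection, the rest
#' for training, normalizer fitted on the training subjects) and predicts
#' all windows of the cohort. Used when a per-sample GDM mask is needed for
#' every subject without running the full leave-one-subject-out loop.
#'
#' @param windows A cohort windows tibble.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param val_frac Fraction of subjects held out for validation.
#' @param params Optional gbt parameter overrides.
#' @return The windows metadata with `score` and `pred` columns.
#' @export
detect_cohort_windows <- function(windows, seed = 1, fs = 25,
                                  val_frac = 0.2, params = NULL) {
  ids <- unique(windows$subject_id)
  n_val <- max(1L, as.integer(ceiling(val_frac * length(ids))))
  val_ids <- .with_seed(seed, sample(ids, n_val))
  idx_val <- windows$subject_id %in% val_ids
  p <- utils::modifyList(.default_gbt_params(), params %||% list())
  mats_raw <- .window_channel_mats(windows)
  mu <- map_dbl(mats_raw, function(m) mean(m[, !idx_val]))
  sdv <- map_dbl(mats_raw, function(m) sd(as.numeric(m[, !idx_val])))
  mats <- map2(mats_raw, seq_along(mats_raw),
               function(m, ch) (m - mu[ch]) / sdv[ch])
  x <- .features_from_mats(mats, fs)
  y <- windows$gdm_label
  weights <- compute_class_weights(y[!idx_val])
  booster <- .train_gbt(x[!idx_val, , drop = FALSE], y[!idx_val],
                        x[idx_val, , drop = FALSE], y[idx_val],
                        weights, seed, p)
  val_scores <- predict(booster, xgboost::xgb.DMatrix(
    x[idx_val, , drop = FALSE]))
  threshold <- select_threshold(val_scores, y[idx_val])
  scores <- predict(booster, xgboost::xgb.DMatrix(x))
  windows %>% select(-"data") %>%
    mutate(score = scores, pred = classify(scores, threshold))
}

#' Per-session GDM sample masks from window predictions
#'
#' @param predictions A predictions tibble (`subject_id`, `side`,
#'   `start_index`, `pred`), e.g. from [detect_cohort_windows()] or the
#'   `predictions` element of [run_loso()].
#' @param kin_cohort The preprocessed cohort the windows came from (supplies
#'   each session's length).
#' @param win_len Window length in samples.
#' @param rule Mask rule, see [gdm_sample_mask()].
#' @return A tibble `subject_id, side, mask` (list-column of logicals).
#' @export
cohort_masks <- function(predictions, kin_cohort, win_len = 75,
                         rule = "majority") {
  rows <- map(seq_len(nrow(kin_cohort)), function(i) {
    id <- kin_cohort$subject_id[i]
    sd_ <- kin_cohort$side[i]
    preds <- predictions %>%
      filter(.data$subject_id == id, .data$side == sd_)
    tibble(subject_id = id, side = sd_,
           mask = list(gdm_sample_mask(preds,
                                       nrow(kin_cohort$kinematics[[i]]),
                                       win_len, rule)))
  })
  bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, preprocess it, window it, evaluate the GDM detector by
#' leave-one-subject-out, rebuild per-sample GDM masks from the held-out
#' predictions, and run the downstream analyses (group classification and
#' FMA regression from GDM-period and entire-recording features, plus the
#' per-feature group statistics table). Each stage logs its counts. All
#' randomness derives from `config$seed`.
#'
#' @param config A [gdm_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `gdm_pipeline` with elements `cohort`, `windows`
#'   (metadata only), `loso`, `clf_gdm`, `clf_entire`, `reg_gdm`,
#'   `reg_entire`, `group_stats`, `config`. Reports are written as JSON/CSV
#'   when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = gdm_config(), quiet = FALSE) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste("Invalid config:", paste(problems, collapse = " ")))
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  spec <- filter_spec(config$low_hz, config$high_hz, config$order)
  win_len <- as.integer(floor(config$win_s * config$fs))

  cohort <- make_cohort(config$n_stroke, config$n_control, config$seed)
  say("simulate: %d subjects (%d stroke, %d control)", nrow(cohort),
      config$n_stroke, config$n_control)
  sessions <- simulate_cohort(cohort, fs_raw = config$fs_raw,
                              seed = config$seed)
  say("simulate: %d sessions", nrow(sessions))
  kin <- preprocess_cohort(sessions, config$fs_raw, config$fs, spec)
  windows <- make_cohort_windows(kin, fs = config$fs, win_s = config$win_s,
                                 overlap = config$overlap,
                                 gdm_fraction = config$gdm_fraction)
  say("windows: %d windows, GDM fraction %.3f", nrow(windows),
      mean(windows$gdm_label))

  loso <- run_loso(windows, seed = config$seed, fs = config$fs,
                   val_frac = config$val_frac, params = config$gbt_params)
  say("evaluate: mean AUC %.3f, balanced accuracy %.3f",
      loso$mean_metrics$auc, loso$mean_metrics$balanced_accuracy)

  masks <- cohort_masks(loso$predictions, kin, win_len, config$mask_rule)
  feats_gdm <- subject_feature_table(kin, masks, config$fs)
  feats_all <- subject_feature_table(kin, NULL, config$fs)
  clf_gdm <- classify_groups(feats_gdm, seed = config$seed)
  clf_entire <- classify_groups(feats_all, seed = config$seed)
  reg_gdm <- regress_fma(feats_gdm, seed = config$seed)
  reg_entire <- regress_fma(feats_all, seed = config$seed)
  say("downstream: balanced accuracy %.2f (GDM) vs %.2f (entire); FMA MAE %.1f vs %.1f",
      clf_gdm$balanced_accuracy, clf_entire$balanced_accuracy,
      reg_gdm$mae, reg_entire$mae)
  group_stats <- group_statistics(feats_gdm)

  out <- structure(
    list(cohort = cohort, windows = windows %>% select(-"data"),
         loso = loso, features_gdm = feats_gdm, features_entire = feats_all,
         clf_gdm = clf_gdm, clf_entire = clf_entire,
         reg_gdm = reg_gdm, reg_entire = reg_entire,
         group_stats = group_stats, config = config),
    class = "gdm_pipeline"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_reports(out, config$out_dir)
    say("reports written to %s", config$out_dir)
  }
  out
}
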