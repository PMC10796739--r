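#' Class weights for an imbalanced GDM/non-GDM training set
#'
#' Each class is weighted by the proportion of the other class, so the
#' minority class contributes as much total weight as the majority class.
#'
#' @param labels Logical (or 0/1) window labels; both classes must occur.
#' @return A list with `w_gdm` and `w_non` (positive, summing to 1).
#' @export
compute_class_weights <- function(labels) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) {
    abort("compute_class_weights needs both classes present.")
  }
  list(w_gdm = mean(!y), w_non = mean(y))
}

#' Select the operating threshold by the geometric-mean rule
#'
#' Scans the midpoints of consecutive sorted unique validation scores and
#' returns the threshold maximising `sqrt(TPR * TNR)` (prediction rule:
#' score >= threshold). Ties are broken toward the lower threshold. Only
#' validation data may be passed here; the test fold never enters threshold
#' selection.
#'
#' @param scores Numeric validation scores.
#' @param labels Logical validation labels; both classes must be present.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  y <- as.logical(labels)
  if (all(y) || !any(y)) {
    abort("select_threshold needs both classes in the validation set.")
  }
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (head(u, -1) + tail(u, -1)) / 2
  np <- sum(y); nn <- sum(!y)
  g <- vapply(cand, function(th) {
    pred <- scores >= th
    sqrt((sum(pred & y) / np) * (sum(!pred & !y) / nn))
  }, numeric(1))
  cand[which.max(g)]
}

.default_gbt_params <- function() {
  list(eta = 0.15, max_depth = 4, nrounds = 150, early_stopping_rounds = 15)
}

# Core gbt fit on feature matrices (used by both the public wrapper and the
# LOSO harness, which precomputes features per fold).
.train_gbt <- function(x_train, y_train, x_val, y_val, weights, seed,
                       params = .default_gbt_params()) {
  w <- ifelse(y_train, weights$w_non, weights$w_gdm)
  dtrain <- xgboost::xgb.DMatrix(x_train, label = as.numeric(y_train),
                                 weight = w)
  dval <- xgboost::xgb.DMatrix(x_val, label = as.numeric(y_val))
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "auc",
                  eta = params$eta, max_depth = params$max_depth,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$nrounds,
    evals = list(val = dval),
    early_stopping_rounds = params$early_stopping_rounds,
    maximize = TRUE, verbose = 0
  )
  booster
}

#' Train a windowed GDM detector
#'
#' The reference backend (`"gbt"`) represents every normalized 6-channel
#' window by its 28-feature descriptor ([window_features()]) and fits
#' gradient-boosted trees with per-window class weights and early stopping on
#' the validation AUC. The operating threshold is then chosen on the
#' validation scores by [select_threshold()].
#'
#' @param train_windows,val_windows Normalized windows tibbles with a
#'   `gdm_label` column; validation must be nonempty and contain both classes.
#' @param backend Only `"gbt"` is implemented.
#' @param seed Integer seed (gbt training is deterministic given the seed).
#' @param fs Sampling rate of the window samples in Hz.
#' @param params Optional list overriding the gbt defaults
#'   (`eta`, `max_depth`, `nrounds`, `early_stopping_rounds`).
#' @return An object of class `gdm_detector`.
#' @export
train_detector <- function(train_windows, val_windows, backend = "gbt",
                           seed = 1, fs = 25, params = NULL) {
  if (backend != "gbt") {
    abort(sprintf("Backend '%s' is not available; use 'gbt'.", backend))
  }
  if (is.null(val_windows) || nrow(val_windows) == 0) {
    abort("Empty validation set: early stopping is undefined.")
  }
  p <- utils::modifyList(.default_gbt_params(), params %||% list())
  y_tr <- train_windows$gdm_label
  y_val <- val_windows$gdm_label
  weights <- compute_class_weights(y_tr)
  x_tr <- window_features(train_windows, fs)
  x_val <- window_features(val_windows, fs)
  booster <- .train_gbt(x_tr, y_tr, x_val, y_val, weights, seed, p)
  val_scores <- predict(booster, xgboost::xgb.DMatrix(x_val))
  threshold <- select_threshold(val_scores, y_val)
  structure(
    list(backend = backend, booster = booster, threshold = threshold,
         weights = weights, fs = fs, feature_names = gdm_feature_names(),
         val_metrics = compute_metrics(y_val, val_scores, threshold)),
    class = "gdm_detector"
  )
}

#' Score windows with a trained detector
#'
#' @param object A `gdm_detector`.
#' @param windows A normalized windows tibble (same normalizer as training);
#'   a heuristic warns when channel scales look un-normalized.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, one per window.
#' @export
predict.gdm_detector <- function(object, windows, ...) {
  probe <- head(windows$data, 50)
  sds <- map_dbl(1:6, function(ch) {
    sd(unlist(map(probe, function(w) w[, ch])))
  })
  if (any(sds > 5 | sds < 0.2)) {
    warn("Window channel scales look un-normalized; did you apply the model's normalizer?")
  }
  x <- window_features(windows, object$fs)
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Threshold detector scores into GDM labels
#'
#' @param scores Numeric scores.
#' @param threshold Operating threshold; a window is GDM when
#'   `score >= threshold`.
#' @return Logical vector.
#' @export
classify <- function(scores, threshold) {
  scores >= threshold
}
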