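#' Tidy a trained detector
#'
#' @param x A `gdm_detector`.
#' @param ... Unused.
#' @return A tibble of feature importances (gain) of the gbt backend.
#' @exportS3Method generics::tidy
tidy.gdm_detector <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble(feature = imp$Feature, gain = imp$Gain, cover = imp$Cover,
         frequency = imp$Frequency)
}

#' @rdname tidy.gdm_detector
#' @exportS3Method generics::glance
glance.gdm_detector <- function(x, ...) {
  bind_cols(tibble(backend = x$backend, threshold = x$threshold),
            x$val_metrics)
}

#' Tidy a leave-one-subject-out evaluation
#'
#' @param x A `gdm_loso`.
#' @param ... Unused.
#' @return `tidy()`: per-split metrics, one row per held-out subject;
#'   `glance()`: the unweighted means across splits.
#' @exportS3Method generics::tidy
tidy.gdm_loso <- function(x, ...) {
  x$split_metrics
}

#' @rdname tidy.gdm_loso
#' @exportS3Method generics::glance
glance.gdm_loso <- function(x, ...) {
  bind_cols(tibble(n_splits = nrow(x$split_metrics)), x$mean_metrics)
}

#' Tidy a group classification result
#'
#' @param x A `gdm_group_clf`.
#' @param ... Unused.
#' @return `tidy()`: mean absolute elastic-net coefficient per feature;
#'   `glance()`: balanced accuracy, sensitivity, specificity.
#' @exportS3Method generics::tidy
tidy.gdm_group_clf <- function(x, ...) {
  arrange(x$coefficients, -.data$mean_abs_coef)
}

#' @rdname tidy.gdm_group_clf
#' @exportS3Method generics::glance
glance.gdm_group_clf <- function(x, ...) {
  tibble(source = x$source,
         balanced_accuracy = x$balanced_accuracy,
         sensitivity = x$sensitivity, specificity = x$specificity)
}

#' Tidy an FMA regression result
#'
#' @param x A `gdm_fma_reg`.
#' @param ... Unused.
#' @return `tidy()`: held-out predictions per subject; `glance()`: MAE,
#'   explained variance, and the FMA standard deviation for reference.
#' @exportS3Method generics::tidy
tidy.gdm_fma_reg <- function(x, ...) {
  x$predictions
}

#' @rdname tidy.gdm_fma_reg
#' @exportS3Method generics::glance
glance.gdm_fma_reg <- function(x, ...) {
  tibble(source = x$source, mae = x$mae,
         explained_variance = x$explained_variance, fma_sd = x$fma_sd)
}

#' @export
print.gdm_loso <- function(x, ...) {
  cat("Leave-one-subject-out GDM detection (", nrow(x$split_metrics),
      " splits)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.gdm_group_clf <- function(x, ...) {
  cat("Stroke vs control elastic-net classification (", x$source, ")\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
print.gdm_fma_reg <- function(x, ...) {
  cat("FMA elastic-net regression (", x$source, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}
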