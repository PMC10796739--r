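#' Empirical ROC curve points
#'
#' @param y_true Logical labels.
#' @param scores Numeric scores.
#' @return A tibble `threshold, tpr, fpr` over the unique scores.
#' @export
roc_curve <- function(y_true, scores) {
  y <- as.logical(y_true)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  np <- sum(y); nn <- sum(!y)
  tibble(
    threshold = th,
    tpr = vapply(th, function(t) sum(scores >= t & y) / np, numeric(1)),
    fpr = vapply(th, function(t) sum(scores >= t & !y) / nn, numeric(1))
  )
}

#' ROC curve of the pooled held-out predictions
#'
#' @param object A `gdm_loso` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gdm_loso <- function(object, ...) {
  rc <- roc_curve(object$predictions$gdm_label, object$predictions$score)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "GDM detection ROC (pooled held-out windows)")
}

#' Coefficient-magnitude plot for a group classification
#'
#' @param object A `gdm_group_clf` result.
#' @param top_n Number of features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gdm_group_clf <- function(object, top_n = 15, ...) {
  dat <- head(tidy(object), top_n)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_abs_coef,
                                    y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean |coefficient| across folds", y = NULL,
                  title = "Elastic-net coefficient magnitudes")
}

#' Effect-size plot for a group-statistics table
#'
#' @param stats A [group_statistics()] tibble.
#' @param ... Unused.
#' @return A ggplot object of Cohen's d per feature, sorted by magnitude.
#' @export
plot_group_statistics <- function(stats, ...) {
  dat <- stats
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cohens_d, y = .data$feature)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cohen's d (stroke - control)", y = NULL,
                  title = "GDM-period feature effect sizes")
}

#' Plot one wrist's raw or preprocessed signal
#'
#' @param session A session or kinematics tibble (columns `t`, `ax`, `ay`,
#'   `az`, optionally `task_type`).
#' @param channels Channels to plot.
#' @return A ggplot object, faceted by channel, shaded by task type when
#'   available.
#' @export
plot_session <- function(session, channels = c("ax", "ay", "az")) {
  long <- tidyr::pivot_longer(session[, c("t", channels)],
                              cols = dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if ("task_type" %in% names(session)) {
    r <- rle(session$task_type)
    ends <- cumsum(r$lengths)
    seg <- tibble(xmin = session$t[c(1L, head(ends, -1) + 1L)],
                  xmax = session$t[ends], task_type = r$values)
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$task_type),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "Time (s)", y = "Acceleration (m/s²)",
                  fill = "Task")
}
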