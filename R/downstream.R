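#' Per-sample GDM mask from window predictions
#'
#' Converts window-level detector output back to the sample level: a sample
#' is GDM when the majority of windows covering it are predicted GDM (ties
#' count as non-GDM; samples covered by no window are non-GDM). An `"any"`
#' rule is available as an alternative.
#'
#' @param window_preds A tibble for one session with `start_index` and `pred`
#'   columns.
#' @param n_samples Session length in samples.
#' @param win_len Window length in samples.
#' @param rule `"majority"` (default) or `"any"`.
#' @return A logical vector of length `n_samples`.
#' @export
gdm_sample_mask <- function(window_preds, n_samples, win_len = 75,
                            rule = c("majority", "any")) {
  rule <- match.arg(rule)
  cover <- integer(n_samples)
  votes <- integer(n_samples)
  for (i in seq_len(nrow(window_preds))) {
    s <- window_preds$start_index[i]
    idx <- s:min(n_samples, s + win_len - 1L)
    cover[idx] <- cover[idx] + 1L
    if (window_preds$pred[i]) votes[idx] <- votes[idx] + 1L
  }
  if (rule == "majority") votes * 2L > cover else votes > 0L
}

#' Subject-level 28-feature descriptor from both wrists
#'
#' Concatenates the (optionally mask-selected) 25 Hz samples of the left and
#' right wrist into one epoch per signal and applies [extract_features()]
#' once, yielding one 28-value row per subject. With `masks = NULL` the
#' entire recording is used.
#'
#' @param kin_pair Two rows of a [preprocess_cohort()] tibble (one subject,
#'   both sides).
#' @param masks Optional list of two logical sample masks (same order as
#'   `kin_pair` rows), e.g. from [gdm_sample_mask()].
#' @param fs Sampling rate in Hz.
#' @return A one-row tibble of the 28 features, or `NULL` (with a warning)
#'   when fewer than 8 samples survive the mask.
#' @export
subject_features <- function(kin_pair, masks = NULL, fs = 25) {
  sides <- sort(unique(kin_pair$side))
  missing <- setdiff(c("left", "right"), sides)
  if (length(missing) > 0) {
    abort(sprintf("Missing wrist session(s): %s",
                  paste(missing, collapse = ", ")))
  }
  pick <- function(i) {
    kin <- kin_pair$kinematics[[i]]
    keep <- if (is.null(masks)) rep(TRUE, nrow(kin)) else masks[[i]]
    kin[keep, , drop = FALSE]
  }
  dat <- bind_rows(pick(1), pick(2))
  if (nrow(dat) < 8) {
    warn(sprintf("Subject %s: fewer than 8 masked samples; excluded.",
                 kin_pair$subject_id[1]))
    return(NULL)
  }
  extract_features(dat[, c("ax", "ay", "az")], dat[, c("vx", "vy", "vz")], fs)
}

#' Subject-level feature table for a whole cohort
#'
#' @param kin_cohort A [preprocess_cohort()] tibble.
#' @param masks Optional tibble with `subject_id`, `side` and a `mask`
#'   list-column of per-sample logical masks (the `gdm_periods` source);
#'   `NULL` uses every sample (the `entire_recording` source).
#' @param fs Sampling rate in Hz.
#' @return A tibble: `subject_id`, `group`, `impairment`, `fma`, `source`,
#'   then the 28 features. Subjects with too few masked samples are dropped
#'   with a warning.
#' @export
subject_feature_table <- function(kin_cohort, masks = NULL, fs = 25) {
  src <- if (is.null(masks)) "entire_recording" else "gdm_periods"
  rows <- map(unique(kin_cohort$subject_id), function(id) {
    pair <- kin_cohort %>% filter(.data$subject_id == id) %>%
      arrange(.data$side)
    m <- if (is.null(masks)) NULL else {
      map(pair$side, function(sd) {
        row <- masks %>% filter(.data$subject_id == id, .data$side == sd)
        if (nrow(row) != 1) abort(sprintf("No mask for %s/%s.", id, sd))
        row$mask[[1]]
      })
    }
    feats <- subject_features(pair, m, fs)
    if (is.null(feats)) return(NULL)
    bind_cols(pair[1, c("subject_id", "group", "impairment", "fma")],
              tibble(source = src), feats)
  })
  bind_rows(rows)
}

# Inner elastic-net fit: small alpha grid, lambda chosen by seeded
# cross-validation on the training fold, features standardized by glmnet
# within the fold.
.fit_enet <- function(x, y, family, seed) {
  # glmnet warns about small binomial groups on every fit; expected at
  # cohort scale (10 controls), so silence just that warning
  withCallingHandlers(
    .fit_enet_impl(x, y, family, seed),
    warning = function(w) {
      if (grepl("dangerous ground|fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

.fit_enet_impl <- function(x, y, family, seed) {
  .with_seed(seed, {
    min_class <- if (family == "binomial") min(table(y)) else Inf
    if (family == "binomial" && min_class < 3) {
      # group too small for nested cross-validation: pick lambda on the
      # alpha = 0.5 path by a BIC-style criterion
      fit <- glmnet::glmnet(x, y, family = family, alpha = 0.5,
                            standardize = TRUE)
      n <- length(y)
      bic <- stats::deviance(fit) + log(n) * fit$df
      lam <- fit$lambda[which.min(bic)]
      return(list(fit = fit, lambda = lam, alpha = 0.5))
    }
    if (family == "binomial") {
      # stratified inner folds so every fold sees both classes
      nf <- min(5, min_class)
      foldid <- integer(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        foldid[idx] <- sample(rep_len(seq_len(nf), length(idx)))
      }
    } else {
      nf <- min(5, nrow(x))
      foldid <- sample(rep_len(seq_len(nf), nrow(x)))
    }
    fits <- map(c(0.1, 0.5, 0.9), function(a) {
      cv <- glmnet::cv.glmnet(x, y, family = family, alpha = a,
                              foldid = foldid, standardize = TRUE,
                              grouped = nrow(x) / nf >= 3)
      list(cv = cv, alpha = a, loss = min(cv$cvm))
    })
    best <- fits[[which.min(map_dbl(fits, "loss"))]]
    list(fit = best$cv, lambda = "lambda.min", alpha = best$alpha)
  })
}

#' Classify stroke versus control from subject features
#'
#' Elastic-net-penalized logistic regression evaluated by
#' leave-one-subject-out: for every held-out subject the penalty mixing and
#' strength are chosen by inner cross-validation on the remaining subjects
#' only. Stroke is the positive class.
#'
#' @param features A [subject_feature_table()] tibble with a `group` column
#'   and at least 3 subjects per group.
#' @param seed Integer seed for the inner cross-validation folds.
#' @return An object of class `gdm_group_clf` with held-out predictions,
#'   balanced accuracy, sensitivity, specificity, and mean absolute
#'   coefficient per feature.
#' @export
classify_groups <- function(features, seed = 1) {
  if (length(unique(features$group)) < 2) {
    abort("classify_groups needs both groups present.")
  }
  if (any(table(features$group) < 3)) {
    abort("classify_groups needs at least 3 subjects per group.")
  }
  x <- as.matrix(features[, gdm_feature_names()])
  y <- as.integer(features$group == "stroke")
  n <- nrow(x)
  prob <- numeric(n)
  coefs <- matrix(0, n, ncol(x), dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n)) {
    fit <- .fit_enet(x[-i, , drop = FALSE], y[-i], "binomial", seed + i)
    prob[i] <- predict(fit$fit, x[i, , drop = FALSE], s = fit$lambda,
                       type = "response")[1]
    coefs[i, ] <- as.numeric(coef(fit$fit, s = fit$lambda))[-1]
  }
  pred <- prob >= 0.5
  sens <- mean(pred[y == 1])
  spec <- mean(!pred[y == 0])
  structure(
    list(predictions = tibble(subject_id = features$subject_id,
                              group = features$group, prob = prob,
                              pred = ifelse(pred, "stroke", "control")),
         balanced_accuracy = (sens + spec) / 2,
         sensitivity = sens, specificity = spec,
         coefficients = tibble(feature = colnames(x),
                               mean_abs_coef = colMeans(abs(coefs))),
         source = unique(features$source)),
    class = "gdm_group_clf"
  )
}

#' Predict the Fugl-Meyer score from subject features
#'
#' Elastic-net linear regression over stroke subjects only, evaluated by
#' leave-one-subject-out. Reports the mean absolute error of the held-out
#' predictions and the explained variance
#' `1 - Var(residual) / Var(fma)` (floored at -1).
#'
#' @param features A [subject_feature_table()] tibble restricted (internally)
#'   to stroke subjects; at least 5 required, with non-constant FMA.
#' @param seed Integer seed for the inner cross-validation folds.
#' @return An object of class `gdm_fma_reg`.
#' @export
regress_fma <- function(features, seed = 1) {
  dat <- features %>% filter(.data$group == "stroke")
  if (nrow(dat) < 5) abort("regress_fma needs at least 5 stroke subjects.")
  if (sd(dat$fma) == 0) abort("FMA is constant; regression undefined.")
  x <- as.matrix(dat[, gdm_feature_names()])
  y <- dat$fma
  pred <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- .fit_enet(x[-i, , drop = FALSE], y[-i], "gaussian", seed + i)
    pred[i] <- predict(fit$fit, x[i, , drop = FALSE], s = fit$lambda)[1]
  }
  resid <- y - pred
  structure(
    list(predictions = tibble(subject_id = dat$subject_id, fma = y,
                              predicted = pred),
         mae = mean(abs(resid)),
         explained_variance = max(-1, 1 - var(resid) / var(y)),
         fma_sd = sd(y),
         source = unique(dat$source)),
    class = "gdm_fma_reg"
  )
}

#' Group summary statistics and effect sizes per feature
#'
#' For every feature: group means and sample standard deviations, Cohen's d
#' with the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` (sign convention
#' stroke minus control), and the two-sided pooled-variance two-sample
#' t-test p-value.
#'
#' @param features A [subject_feature_table()] tibble with a `group` column;
#'   both groups must have at least 2 subjects.
#' @return A tibble `feature, stroke_mean, stroke_sd, control_mean,
#'   control_sd, cohens_d, p_value`, sorted by `abs(cohens_d)` descending.
#' @export
group_statistics <- function(features) {
  g1 <- features %>% filter(.data$group == "stroke")
  g2 <- features %>% filter(.data$group == "control")
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    abort("group_statistics needs at least 2 subjects per group.")
  }
  rows <- map(gdm_feature_names(), function(f) {
    cohens_d_summary(mean(g1[[f]]), sd(g1[[f]]), nrow(g1),
                     mean(g2[[f]]), sd(g2[[f]]), nrow(g2)) %>%
      mutate(feature = f, .before = 1)
  })
  bind_rows(rows) %>% arrange(-abs(.data$cohens_d))
}

#' Cohen's d and pooled-variance t-test from group summaries
#'
#' Computes the standardized mean difference and two-sided p-value directly
#' from group means, standard deviations and sizes, so it applies equally to
#' raw data summaries and to published summary tables.
#'
#' @param m1,s1,n1 Mean, sample SD and size of the first (stroke) group.
#' @param m2,s2,n2 Mean, sample SD and size of the second (control) group.
#' @return A one-row tibble `stroke_mean, stroke_sd, control_mean,
#'   control_sd, cohens_d, p_value`.
#' @export
cohens_d_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  tibble(stroke_mean = m1, stroke_sd = s1, control_mean = m2,
         control_sd = s2, cohens_d = d, p_value = p)
}
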