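test_that("sample masks follow the majority vote over covering windows", {
  preds <- tibble::tibble(start_index = c(1, 23, 45), pred = c(TRUE, TRUE, TRUE))
  m <- gdm_sample_mask(preds, n_samples = 150, win_len = 75)
  expect_true(all(m[1:119]))
  expect_false(any(m[120:150]))
  expect_false(any(gdm_sample_mask(preds[0, ], 150)))

  # alternating predictions: oracle recount per sample
  preds2 <- tibble::tibble(start_index = seq(1, 120, by = 22),
                           pred = rep(c(TRUE, FALSE), 3))
  m2 <- gdm_sample_mask(preds2, 200, 75)
  for (i in c(1, 30, 60, 90, 120, 150, 199)) {
    covering <- preds2$start_index <= i & preds2$start_index + 74 >= i
    oracle <- sum(preds2$pred[covering]) * 2 > sum(covering)
    expect_equal(m2[i], oracle)
  }
  # "any" rule marks every covered sample with one positive window
  m3 <- gdm_sample_mask(preds2, 200, 75, rule = "any")
  expect_true(all(m3[m2]))
})

test_that("subject features honour masks and both-wrist requirements", {
  kin <- mini_cohort()$kin
  pair <- kin[kin$subject_id == kin$subject_id[1], ]
  all_true <- lapply(pair$kinematics, function(k) rep(TRUE, nrow(k)))
  f_masked <- subject_features(pair, all_true)
  f_entire <- subject_features(pair, NULL)
  expect_equal(f_masked, f_entire)
  expect_error(subject_features(pair[1, ]), "right|left")
  tiny <- lapply(pair$kinematics, function(k) {
    m <- rep(FALSE, nrow(k)); m[1:3] <- TRUE; m
  })
  expect_warning(out <- subject_features(pair, tiny), "excluded")
  expect_null(out)
})

test_that("group classification recovers a perfectly informative feature", {
  feats <- synthetic_feature_table(informative = TRUE)
  clf <- classify_groups(feats, seed = 2)
  expect_equal(clf$balanced_accuracy, 1)
  expect_error(classify_groups(feats[feats$group == "stroke", ], seed = 1),
               "both groups")
})

test_that("uninformative features classify shuffled labels at chance", {
  # unequal groups as in the study design; with equal groups the held-out
  # subject's class is always the training minority and leave-one-out
  # accuracy is pessimistically biased below chance
  feats <- synthetic_feature_table(n_stroke = 10, n_control = 6,
                                   informative = FALSE)
  set.seed(31)
  accs <- replicate(20, {
    shuf <- feats
    shuf$group <- sample(shuf$group)
    if (min(table(shuf$group)) < 3) return(NA_real_)
    classify_groups(shuf, seed = sample.int(1000, 1))$balanced_accuracy
  })
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.15)
})

test_that("FMA regression recovers linear signal and rejects noise", {
  feats <- synthetic_feature_table(n_stroke = 15, n_control = 3, seed = 9,
                                   informative = FALSE)
  feats$fma[feats$group == "stroke"] <-
    40 + 10 * feats$acc_rms[feats$group == "stroke"] +
    rnorm(15, sd = 0.05)
  reg <- regress_fma(feats, seed = 2)
  expect_gt(reg$explained_variance, 0.95)
  expect_lt(reg$mae, reg$fma_sd)

  noise <- synthetic_feature_table(n_stroke = 15, n_control = 3, seed = 10,
                                   informative = FALSE)
  noise$fma[noise$group == "stroke"] <- round(runif(15, 20, 60))
  reg_noise <- regress_fma(noise, seed = 2)
  expect_lt(reg_noise$explained_variance, 0.2)
  expect_gte(reg_noise$explained_variance, -1)

  const <- noise
  const$fma[const$group == "stroke"] <- 30
  expect_error(regress_fma(const, seed = 1), "constant")
  expect_error(regress_fma(noise[noise$group == "stroke", ][1:4, ]),
               "at least 5")
})

test_that("Cohen's d matches published worked examples from summaries", {
  # printed summary pairs with n = (20, 10)
  r1 <- cohens_d_summary(0.21, 0.1, 20, 0.5, 0.11, 10)
  expect_equal(round(r1$cohens_d, 2), -2.81)
  r2 <- cohens_d_summary(75.61, 43.6, 20, 32.13, 5.1, 10)
  expect_equal(round(r2$cohens_d, 2), 1.21)
  # identical groups
  r3 <- cohens_d_summary(5, 1, 20, 5, 1, 10)
  expect_equal(r3$cohens_d, 0)
  expect_equal(r3$p_value, 1)
})

test_that("group statistics are antisymmetric and affine-invariant", {
  feats <- synthetic_feature_table(informative = TRUE)
  gs <- group_statistics(feats)
  expect_equal(nrow(gs), 28)
  expect_true(all(is.finite(gs$cohens_d)))
  expect_true(all(gs$p_value > 0 & gs$p_value <= 1))
  # swap groups: d flips sign
  swapped <- feats
  swapped$group <- ifelse(feats$group == "stroke", "control", "stroke")
  gss <- group_statistics(swapped)
  ord <- match(gs$feature, gss$feature)
  expect_equal(gss$cohens_d[ord], -gs$cohens_d)
  # common affine rescaling of a feature leaves d unchanged
  scaled <- feats
  scaled$acc_rms <- 3 * scaled$acc_rms + 7
  gs2 <- group_statistics(scaled)
  expect_equal(gs2$cohens_d[gs2$feature == "acc_rms"],
               gs$cohens_d[gs$feature == "acc_rms"])
  one <- feats[c(1, which(feats$group == "control")), ]
  expect_error(group_statistics(one), "at least 2")
})
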