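test_that("LOSO split plans partition the cohort with a 10% validation set", {
  ids <- sprintf("P%02d", 1:30)
  plans <- loso_splits(ids, seed = 5)
  expect_equal(nrow(plans), 30)
  for (k in seq_len(nrow(plans))) {
    expect_length(plans$validation_subjects[[k]], 3) # ceil(0.1 * 29)
    all_ids <- c(plans$test_subject[k], plans$validation_subjects[[k]],
                 plans$train_subjects[[k]])
    expect_setequal(all_ids, ids)
    expect_equal(length(all_ids), 30) # disjoint
  }
  tiny <- loso_splits(c("a", "b", "c"), seed = 1)
  expect_equal(nrow(tiny), 3)
  expect_length(tiny$validation_subjects[[1]], 1)
  expect_length(tiny$train_subjects[[1]], 1)
  expect_error(loso_splits(c("a", "b"), seed = 1), "3 subjects")
})

test_that("metrics match their definitions and the pair-counting AUC oracle", {
  y <- c(rep(TRUE, 10), rep(FALSE, 10))
  perfect <- compute_metrics(y, as.numeric(y), 0.5)
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1, 1))
  anti <- compute_metrics(y, 1 - as.numeric(y), 0.5)
  expect_equal(anti$auc, 0)

  # printed-table identity: balanced accuracy is the mean of sens and spec
  scores <- c(rep(1, 81), rep(0, 19), rep(0, 84), rep(1, 16))
  truth <- rep(c(TRUE, FALSE), each = 100)
  m <- compute_metrics(truth, scores, 0.5)
  expect_equal(m$sensitivity, 0.81)
  expect_equal(m$specificity, 0.84)
  expect_equal(m$balanced_accuracy, 0.825)

  # AUC equals the tie-aware pair-counting oracle
  auc_oracle <- function(y, s) {
    pos <- s[y]; neg <- s[!y]
    total <- 0
    for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
    total / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- runif(n) < 0.3
    if (all(y) || !any(y)) next
    s <- round(runif(n), 2)
    expect_equal(compute_metrics(y, s, 0.5)$auc, auc_oracle(y, s))
  }

  expect_warning(m1 <- compute_metrics(rep(TRUE, 5), runif(5), 0.5),
                 "single-class")
  expect_true(is.na(m1$auc))
  expect_false(is.na(m1$sensitivity))
})

test_that("per-task accuracy aggregates cells correctly", {
  preds <- tibble::tibble(
    group = c(rep("stroke", 4), rep("control", 2)),
    side_role = "affected",
    task_context = c(rep("bimanual", 4), rep("passive", 2)),
    gdm_label = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    pred = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  tab <- per_task_accuracy(preds)
  expect_equal(tab$accuracy[tab$group == "stroke"], 0.75)
  expect_equal(tab$accuracy[tab$group == "control"], 1)
  all_right <- per_task_accuracy(dplyr::mutate(preds, pred = gdm_label))
  expect_true(all(all_right$accuracy == 1))
})

test_that("run_loso nails separable data and never leaks the test subject", {
  w <- separable_windows(80, n_subjects = 4)
  res <- run_loso(w, seed = 2)
  expect_equal(nrow(res$split_metrics), 4)
  expect_gt(res$mean_metrics$auc, 0.95)
  expect_gt(res$mean_metrics$balanced_accuracy, 0.9)
  # leak check: corrupting one subject's windows must not move the
  # threshold of the fold where that subject is the test subject
  w2 <- w
  hit <- w2$subject_id == "T01"
  w2$data[hit] <- lapply(w2$data[hit], function(m) m * 100 + 5)
  res2 <- run_loso(w2, seed = 2)
  th1 <- res$split_metrics$threshold[res$split_metrics$test_subject == "T01"]
  th2 <- res2$split_metrics$threshold[res2$split_metrics$test_subject == "T01"]
  expect_equal(th1, th2)
})

test_that("LOSO reports round-trip through JSON", {
  w <- separable_windows(40, n_subjects = 3)
  res <- run_loso(w, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_loso_report(res, path)
  back <- read_loso_report(path)
  expect_equal(back$split_metrics, res$split_metrics, tolerance = 1e-12)
  expect_equal(back$mean_metrics, res$mean_metrics, tolerance = 1e-12)
  expect_equal(back$seed, res$seed)
})
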