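test_that("make_cohort builds the requested groups deterministically", {
  cohort <- make_cohort(20, 10, seed = 4)
  expect_equal(nrow(cohort), 30)
  expect_equal(sum(cohort$impairment == 0), 10)
  expect_true(all(cohort$impairment[cohort$group == "stroke"] > 0))
  expect_true(all(cohort$fma >= 10 & cohort$fma <= 66))
  expect_equal(cohort, make_cohort(20, 10, seed = 4))
  expect_equal(nrow(make_cohort(0, 0, seed = 1)), 0)
  expect_error(make_cohort(-1, 5, seed = 1), "counts")
})

test_that("simulated FMA matches the target clinical distribution", {
  big <- make_cohort(2000, 0, seed = 8)
  expect_lt(abs(mean(big$fma) - 37), 2)
  expect_lt(abs(sd(big$fma) - 8), 2)
})

test_that("minimum-jerk reaches have the textbook kinematic properties", {
  fs <- 100
  reach <- minimum_jerk_reach(0.4, 1.2, fs, direction = c(1, 0, 0))
  # starts and ends at rest
  expect_lt(abs(reach[1, 1]), 1e-10)
  expect_lt(abs(reach[nrow(reach), 1]), 1e-10)
  # net velocity change over the reach is zero
  expect_lt(abs(sum(reach[, 1]) / fs), 0.01)
  # peak speed: maximize the speed polynomial on a fine grid (oracle)
  tau <- seq(0, 1, length.out = 10001)
  peak_oracle <- max((0.4 / 1.2) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4))
  expect_equal(peak_oracle, 1.875 * 0.4 / 1.2, tolerance = 1e-6)
  vel <- cumsum(reach[, 1]) / fs
  expect_equal(max(vel), peak_oracle, tolerance = 0.01)
  expect_error(minimum_jerk_reach(0.4, 0, fs), "duration")
})

test_that("simulate_session is deterministic and respects the script", {
  subj <- make_cohort(1, 0, seed = 2)[1, ]
  script <- default_task_script(subj$affected_side)
  s1 <- simulate_session(subj, script, "left", 100, seed = 5)
  s2 <- simulate_session(subj, script, "left", 100, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, simulate_session(subj, script, "left", 100, seed = 6)))
  # per-sample label durations equal script durations to within one sample
  durations <- rle(paste(s1$task_type, s1$role))$lengths / 100
  # the passive-side unimanual block is relabelled task_free, merge adjacent
  expect_equal(sum(durations), sum(script$duration))
  expect_equal(nrow(s1), sum(script$duration) * 100)
  expect_error(
    simulate_session(subj, script[0, ], "left", 100, seed = 1), "duration")
  expect_error(
    simulate_session(subj, script, "left", fs_raw = 40, seed = 1), "fs_raw")
})

test_that("task-free signal is quieter than GDM signal after gravity removal", {
  subj <- make_cohort(1, 0, seed = 3)[1, ]
  subj$impairment <- 0
  script <- default_task_script(subj$affected_side)
  sess <- simulate_session(subj, script, subj$affected_side, 100, seed = 9)
  acc <- bandpass(sess[, c("ax", "ay", "az")], 100)
  mag <- magnitude(acc)
  gdm <- gdm_ground_truth(sess)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(mag[sess$task_type == "task_free"]), rms(mag[gdm]))
})

test_that("the passive side of unimanual blocks is labelled task-free", {
  subj <- make_cohort(1, 0, seed = 2)[1, ]
  script <- tibble::tibble(task_type = "unimanual", duration = 10,
                           active_side = subj$affected_side)
  other <- if (subj$affected_side == "left") "right" else "left"
  passive_side <- simulate_session(subj, script, other, 100, seed = 1)
  expect_true(all(passive_side$task_type == "task_free"))
  active_side <- simulate_session(subj, script, subj$affected_side, 100,
                                  seed = 1)
  expect_true(all(active_side$task_type == "unimanual"))
  expect_true(all(active_side$role == "active"))
})

test_that("impairment leaves the expected signature on GDM-period features", {
  # paired subjects: identical seeds, impairment toggled
  subj <- make_cohort(1, 0, seed = 12)[1, ]
  script <- default_task_script(subj$affected_side)
  impaired <- subj
  impaired$impairment <- 0.8
  feats <- lapply(list(subj, impaired), function(s) {
    sess <- simulate_session(s, script, s$affected_side, 100, seed = 21)
    kin <- preprocess_session(sess)
    mask <- gdm_ground_truth(kin)
    extract_features(kin[mask, c("ax", "ay", "az")],
                     kin[mask, c("vx", "vy", "vz")], 25)
  })
  expect_gt(feats[[2]]$acc_crossing_number, feats[[1]]$acc_crossing_number)
  expect_lt(feats[[2]]$acc_rms, feats[[1]]$acc_rms)
})
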