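# Shared fixtures built in code. The heavier simulated objects are cached so
# that several test files can reuse one small cohort.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small simulated cohort (4 stroke + 3 control), preprocessed and windowed.
mini_cohort <- function() {
  cached("mini", function() {
    cohort <- make_cohort(4, 3, seed = 101)
    sessions <- simulate_cohort(cohort, seed = 101)
    kin <- preprocess_cohort(sessions)
    windows <- make_cohort_windows(kin)
    list(cohort = cohort, sessions = sessions, kin = kin, windows = windows)
  })
}

# Synthetic, trivially separable windows: "movement" windows carry a strong
# sinusoid, "rest" windows only weak noise. Returns a windows tibble in the
# same shape make_cohort_windows() produces.
separable_windows <- function(n_per_class = 60, n_subjects = 4, seed = 7) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tt <- seq_len(75) / 25
    mk <- function(label) {
      base <- if (label) {
        vapply(1:6, function(j) {
          2 * sin(2 * pi * runif(1, 0.5, 2) * tt + runif(1, 0, 6))
        }, numeric(75))
      } else {
        matrix(0, 75, 6)
      }
      base + matrix(rnorm(75 * 6, sd = 0.3), 75, 6)
    }
    labels <- rep(c(TRUE, FALSE), each = n_per_class)
    tibble::tibble(
      subject_id = rep_len(sprintf("T%02d", seq_len(n_subjects)),
                           2 * n_per_class),
      group = "stroke",
      side = "left",
      side_role = "affected",
      start_index = seq_len(2 * n_per_class),
      task_context = ifelse(labels, "bimanual", "task_free"),
      gdm_label = labels,
      data = lapply(labels, mk)
    )
  })
}

# Subject-level feature table with a synthetic, perfectly informative column.
synthetic_feature_table <- function(n_stroke = 8, n_control = 8, seed = 3,
                                    informative = TRUE) {
  set.seed(seed)
  n <- n_stroke + n_control
  x <- matrix(rnorm(n * 28), n, 28,
              dimnames = list(NULL, gdm_feature_names()))
  group <- rep(c("stroke", "control"), c(n_stroke, n_control))
  if (informative) {
    x[, "acc_crossing_number"] <- ifelse(group == "stroke", 5, -5) +
      rnorm(n, sd = 0.1)
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("X%02d", seq_len(n)), group = group,
                   impairment = ifelse(group == "stroke", 0.6, 0),
                   fma = ifelse(group == "stroke",
                                round(40 + rnorm(n, 0, 5)), 66),
                   source = "gdm_periods"),
    tibble::as_tibble(x)
  )
}
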