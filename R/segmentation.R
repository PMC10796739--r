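#' Per-sample GDM ground truth from task labels
#'
#' The labelling rule: bimanual samples and active-side unimanual samples are
#' goal-directed movement (GDM); passive-side unimanual, passive, and
#' task-free samples are non-GDM.
#'
#' @param labels A data frame with character columns `task_type`
#'   (`unimanual`, `bimanual`, `passive`, `task_free`) and `role`
#'   (`active`, `passive`, `none`).
#' @return A logical vector, one element per sample.
#' @export
gdm_ground_truth <- function(labels) {
  tt <- labels$task_type
  bad <- setdiff(unique(tt), c("unimanual", "bimanual", "passive", "task_free"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown task_type: %s", paste(bad, collapse = ", ")))
  }
  tt == "bimanual" | (tt == "unimanual" & labels$role == "active")
}

#' Segment kinematics into labelled sliding windows
#'
#' Cuts one wrist's 25 Hz kinematics into windows of `win_s` seconds with
#' fractional `overlap` (default 3 s, 70%: 75 samples, hop
#' `floor(75 * 0.3) = 22`). A window is labelled GDM when at least one third
#' of its samples are GDM. Inputs shorter than one window yield an empty
#' windows tibble.
#'
#' @param kinematics A tibble with columns `ax, ay, az, vx, vy, vz` (and
#'   optionally `task_type`) at `fs`.
#' @param gdm_mask Logical per-sample GDM ground truth
#'   (see [gdm_ground_truth()]).
#' @param fs Sampling rate in Hz.
#' @param win_s Window length in seconds; a fractional `win_s * fs` is
#'   floored to whole samples.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param gdm_fraction Labelling threshold (default 1/3, inclusive).
#' @return A tibble with `start_index` (1-based first sample),
#'   `gdm_label`, `task_context` (modal task type in the window, if
#'   available) and a `data` list-column of `win_len x 6` matrices.
#' @export
make_windows <- function(kinematics, gdm_mask, fs = 25, win_s = 3,
                         overlap = 0.7, gdm_fraction = 1 / 3) {
  win_len <- as.integer(floor(win_s * fs))
  if (win_len < 2) abort("win_s * fs must cover at least 2 samples.")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1).")
  hop <- max(1L, as.integer(floor(win_len * (1 - overlap))))
  m <- as.matrix(kinematics[, c("ax", "ay", "az", "vx", "vy", "vz")])
  n <- nrow(m)
  if (length(gdm_mask) != n) {
    abort("gdm_mask length must equal the number of samples.")
  }
  if (n < win_len) {
    return(tibble(start_index = integer(), gdm_label = logical(),
                  task_context = character(), data = list()))
  }
  starts <- seq.int(1L, n - win_len + 1L, by = hop)
  has_task <- "task_type" %in% names(kinematics)
  out <- map(starts, function(s) {
    idx <- s:(s + win_len - 1L)
    ctx <- if (has_task) {
      names(which.max(table(kinematics$task_type[idx])))
    } else NA_character_
    list(start_index = s,
         gdm_label = mean(gdm_mask[idx]) >= gdm_fraction,
         task_context = ctx,
         data = m[idx, , drop = FALSE])
  })
  tibble(
    start_index = map_int(out, "start_index"),
    gdm_label = map_lgl(out, "gdm_label"),
    task_context = map_chr(out, "task_context"),
    data = map(out, "data")
  )
}

#' Window a preprocessed cohort
#'
#' Applies [gdm_ground_truth()] and [make_windows()] to every (subject, side)
#' session of a preprocessed cohort, each wrist windowed separately.
#'
#' @param kin_cohort Output of [preprocess_cohort()].
#' @param fs,win_s,overlap,gdm_fraction Passed to [make_windows()].
#' @return One windows tibble for the whole cohort, with subject metadata
#'   columns alongside `start_index`, `gdm_label`, `task_context`, `data`.
#' @export
make_cohort_windows <- function(kin_cohort, fs = 25, win_s = 3, overlap = 0.7,
                                gdm_fraction = 1 / 3) {
  rows <- map(seq_len(nrow(kin_cohort)), function(i) {
    kin <- kin_cohort$kinematics[[i]]
    w <- make_windows(kin, gdm_ground_truth(kin), fs = fs, win_s = win_s,
                      overlap = overlap, gdm_fraction = gdm_fraction)
    if (nrow(w) == 0) return(NULL)
    bind_cols(
      kin_cohort[rep(i, nrow(w)), c("subject_id", "group", "impairment",
                                    "fma", "side", "side_role")],
      w
    )
  })
  bind_rows(rows)
}

#' Fit a per-channel window normalizer on a training split
#'
#' Pools all samples of all training windows per channel and records the mean
#' and standard deviation, the statistics later subtracted/divided out of
#' every split's windows.
#'
#' @param windows A windows tibble (at least 2 windows).
#' @return An object of class `gdm_normalizer` with `mean` and `sd` vectors
#'   (length 6).
#' @export
fit_normalizer <- function(windows) {
  if (nrow(windows) < 2) abort("fit_normalizer needs at least 2 windows.")
  mats <- .window_channel_mats(windows)
  mu <- map_dbl(mats, mean)
  sdv <- map_dbl(mats, function(m) sd(as.numeric(m)))
  ch <- c("ax", "ay", "az", "vx", "vy", "vz")
  if (any(sdv == 0)) {
    abort(sprintf("Zero-variance channel(s): %s",
                  paste(ch[sdv == 0], collapse = ", ")))
  }
  structure(list(mean = stats::setNames(mu, ch),
                 sd = stats::setNames(sdv, ch)),
            class = "gdm_normalizer")
}

#' Apply a fitted normalizer to windows
#'
#' @param normalizer A [fit_normalizer()] object.
#' @param windows A windows tibble.
#' @return The windows tibble with each channel of each window transformed to
#'   `(x - mean) / sd`.
#' @export
apply_normalizer <- function(normalizer, windows) {
  mu <- normalizer$mean
  sdv <- normalizer$sd
  windows$data <- map(windows$data, function(w) {
    sweep(sweep(w, 2, mu), 2, sdv, "/")
  })
  windows
}
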