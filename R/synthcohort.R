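# Run code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generate a synthetic study cohort
#'
#' Creates subject records for a stroke group and a control group. Stroke
#' impairment is drawn from Uniform(0.3, 0.9) on a 0 (unimpaired) to 1 scale,
#' and the upper-extremity Fugl-Meyer score (FMA, 0-66) is linked to
#' impairment by a calibrated linear map with rater noise,
#' `round(61 - 40 * impairment + N(0, 4))` clipped to 10-66, so a large
#' stroke group has FMA mean 37 and SD 8. Controls have impairment 0 and
#' FMA 66; their non-dominant wrist plays the role of the affected side.
#'
#' @param n_stroke,n_control Non-negative subject counts.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A tibble with columns `subject_id`, `group`, `impairment`, `fma`,
#'   `affected_side`.
#' @export
make_cohort <- function(n_stroke = 20, n_control = 10, seed = 1) {
  if (n_stroke < 0 || n_control < 0) abort("Subject counts must be >= 0.")
  .with_seed(seed, {
    stroke <- if (n_stroke > 0) {
      imp <- runif(n_stroke, 0.3, 0.9)
      tibble(
        subject_id = sprintf("S%03d", seq_len(n_stroke)),
        group = "stroke",
        impairment = imp,
        fma = pmin(66, pmax(10, round(61 - 40 * imp + rnorm(n_stroke, 0, 4)))),
        affected_side = sample(c("left", "right"), n_stroke, replace = TRUE)
      )
    } else NULL
    control <- if (n_control > 0) {
      dominant <- sample(c("right", "left"), n_control, replace = TRUE,
                         prob = c(0.9, 0.1))
      tibble(
        subject_id = sprintf("C%03d", seq_len(n_control)),
        group = "control",
        impairment = 0,
        fma = 66,
        affected_side = ifelse(dominant == "right", "left", "right")
      )
    } else NULL
    out <- bind_rows(stroke, control)
    if (is.null(out)) {
      out <- tibble(subject_id = character(), group = character(),
                    impairment = numeric(), fma = numeric(),
                    affected_side = character())
    }
    out
  })
}

#' Minimum-jerk reach acceleration segment
#'
#' The standard kinematic model of a goal-directed reach: along-movement
#' position `s(tau) = d (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = t / duration`, whose analytic second derivative gives a smooth,
#' bell-shaped acceleration-deceleration profile that starts and ends at rest.
#' Peak speed is `1.875 d / duration` at the movement midpoint.
#'
#' @param distance Reach distance in m (> 0).
#' @param duration Movement time in s (> 0).
#' @param fs Sampling rate in Hz.
#' @param direction Optional unit 3-vector; if `NULL`, a random direction is
#'   drawn from the caller's RNG stream.
#' @return A matrix (`round(duration * fs)` x 3) of acceleration in m/s^2.
#' @export
minimum_jerk_reach <- function(distance, duration, fs, direction = NULL) {
  if (duration <= 0) abort("duration must be positive.")
  if (distance <= 0) abort("distance must be positive.")
  if (is.null(direction)) {
    v <- rnorm(3)
    direction <- v / sqrt(sum(v^2))
  }
  n <- max(2L, as.integer(round(duration * fs)))
  tau <- seq(0, 1, length.out = n)
  a <- (distance / duration^2) * (60 * tau - 180 * tau^2 + 120 * tau^3)
  outer(a, direction)
}

# AR(1)-coloured noise matrix (n x 3) scaled to a per-axis RMS.
.colored_noise <- function(n, rms, phi = 0.9) {
  m <- vapply(1:3, function(j) {
    x <- as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
    x * rms / max(sqrt(mean(x^2)), 1e-12)
  }, numeric(n))
  m
}

# Train of minimum-jerk reaches with impairment effects: reduced amplitude,
# 4-6 Hz tremor, and corrective sub-movements whose rate grows with
# impairment (more direction reversals, lower RMS -- the contrasts the
# downstream group statistics should show).
.gdm_segment <- function(n, fs, impairment) {
  acc <- .colored_noise(n, 0.05)
  amp <- 1 - 0.5 * impairment
  cur <- 1L
  while (cur < n) {
    dur <- runif(1, 0.5, 1.5)
    reach <- minimum_jerk_reach(runif(1, 0.2, 0.6), dur, fs) * amp
    k <- min(nrow(reach), n - cur + 1L)
    acc[cur:(cur + k - 1L), ] <- acc[cur:(cur + k - 1L), ] + reach[1:k, ]
    cur <- cur + nrow(reach) + as.integer(round(runif(1, 0.2, 0.6) * fs))
  }
  if (impairment > 0) {
    f <- runif(1, 4, 6)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    trem <- 0.12 * impairment *
      sin(2 * pi * f * seq_len(n) / fs + runif(1, 0, 2 * pi))
    acc <- acc + outer(trem, v)
    n_sub <- rpois(1, 3 * impairment * n / fs)
    if (n_sub > 0) {
      for (i in seq_len(n_sub)) {
        sub <- minimum_jerk_reach(runif(1, 0.005, 0.015),
                                  runif(1, 0.3, 0.5), fs)
        pos <- sample.int(n, 1)
        k <- min(nrow(sub), n - pos + 1L)
        acc[pos:(pos + k - 1L), ] <- acc[pos:(pos + k - 1L), ] + sub[1:k, ]
      }
    }
  }
  acc
}

# Gait-like sinusoidal arm swing at 1.8-2.2 Hz.
.passive_segment <- function(n, fs) {
  f <- runif(1, 1.8, 2.2)
  ampl <- runif(1, 1.0, 2.0)
  v <- rnorm(3); v <- v / sqrt(sum(v^2))
  outer(ampl * sin(2 * pi * f * seq_len(n) / fs + runif(1, 0, 2 * pi)), v) +
    .colored_noise(n, 0.05)
}

.taskfree_segment <- function(n, fs) {
  .colored_noise(n, runif(1, 0.08, 0.15))
}

#' Default activities-of-daily-living task script
#'
#' A fixed 150 s sequence of task-free, unimanual, passive and bimanual
#' segments whose boundaries align to the 2.5 s labelling granularity and
#' whose per-wrist GDM sample fraction is roughly 0.22.
#'
#' @param affected_side `"left"` or `"right"`; the side performing unimanual
#'   tasks (the other side gets one shorter unimanual block).
#' @return A tibble with columns `task_type`, `duration`, `active_side`.
#' @export
default_task_script <- function(affected_side = "left") {
  other <- if (affected_side == "left") "right" else "left"
  tibble(
    task_type  = c("task_free", "unimanual", "passive", "bimanual",
                   "task_free", "unimanual", "passive", "bimanual",
                   "task_free"),
    duration   = c(25, 12.5, 20, 12.5, 25, 10, 15, 10, 20),
    active_side = c("none", affected_side, "none", "both",
                    "none", other, "none", "both", "none")
  )
}

#' Simulate one wrist's raw accelerometer session
#'
#' Builds the raw tri-axial signal for one wrist following a task script:
#' goal-directed segments are trains of minimum-jerk reaches (degraded with
#' impairment), passive segments are 1.8-2.2 Hz arm-swing oscillations,
#' task-free segments are low-amplitude coloured noise, and a 9.81 m/s^2
#' gravity vector with slow orientation drift is added throughout. The wrist
#' opposite to a unimanual task carries task-free-like signal and is labelled
#' `task_free` (the labelling convention for the passive side).
#'
#' @param subject One row of a [make_cohort()] tibble.
#' @param script A task script tibble (see [default_task_script()]).
#' @param side `"left"` or `"right"`.
#' @param fs_raw Raw sampling rate in Hz (>= 50 so downsampling to 25 Hz is
#'   meaningful).
#' @param seed Integer seed; output is deterministic given all arguments.
#' @param activity_scale Subject-specific multiplier on the non-GDM signal
#'   amplitude (arm-swing and task-free noise), modelling how much overall
#'   incidental movement a person produces independent of impairment.
#' @return A session tibble `t, ax, ay, az, task_type, role` at `fs_raw`.
#' @export
simulate_session <- function(subject, script, side, fs_raw = 100, seed = 1,
                             activity_scale = 1) {
  if (fs_raw < 50) abort("fs_raw must be >= 50 Hz.")
  if (sum(script$duration) <= 0) abort("script has zero total duration.")
  if (any(script$duration <= 0)) abort("script durations must be positive.")
  .with_seed(seed, {
    # the unaffected side of a stroke subject retains a mild deficit
    imp <- if (side == subject$affected_side) subject$impairment else
      0.3 * subject$impairment
    segs <- pmap(script, function(task_type, duration, active_side) {
      n <- as.integer(round(duration * fs_raw))
      if (task_type == "bimanual") {
        list(acc = .gdm_segment(n, fs_raw, imp), task = "bimanual",
             role = "active")
      } else if (task_type == "unimanual") {
        if (active_side == side) {
          list(acc = .gdm_segment(n, fs_raw, imp), task = "unimanual",
               role = "active")
        } else {
          list(acc = activity_scale * .taskfree_segment(n, fs_raw),
               task = "task_free", role = "none")
        }
      } else if (task_type == "passive") {
        list(acc = activity_scale * .passive_segment(n, fs_raw),
             task = "passive", role = "passive")
      } else if (task_type == "task_free") {
        list(acc = activity_scale * .taskfree_segment(n, fs_raw),
             task = "task_free", role = "none")
      } else {
        abort(sprintf("Unknown task_type '%s'.", task_type))
      }
    })
    acc <- do.call(rbind, map(segs, "acc"))
    n <- nrow(acc)
    tt <- seq_len(n) / fs_raw
    # slowly drifting gravity orientation (periods ~1 min, a few degrees)
    theta <- 0.15 + 0.05 * sin(2 * pi * tt / runif(1, 50, 70) +
                                 runif(1, 0, 2 * pi))
    psi <- runif(1, 0, 2 * pi) + 0.05 * sin(2 * pi * tt / runif(1, 40, 80))
    grav <- 9.81 * cbind(sin(theta) * cos(psi), sin(theta) * sin(psi),
                         cos(theta))
    acc <- acc + grav
    tibble(
      t = (seq_len(n) - 1L) / fs_raw,
      ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
      task_type = rep(map_chr(segs, "task"),
                      map_int(segs, ~ nrow(.x$acc))),
      role = rep(map_chr(segs, "role"), map_int(segs, ~ nrow(.x$acc)))
    )
  })
}

#' Simulate both wrists for a whole cohort
#'
#' @param cohort A [make_cohort()] tibble.
#' @param script Optional task script; defaults to [default_task_script()]
#'   oriented to each subject's affected side.
#' @param fs_raw Raw sampling rate in Hz.
#' @param seed Integer seed; per-session seeds are derived from it.
#' @return A nested tibble, one row per (subject, side), with subject
#'   metadata, `side`, `side_role` (affected/unaffected for stroke,
#'   non-dominant/dominant for controls) and a `raw` session list-column.
#' @export
simulate_cohort <- function(cohort, script = NULL, fs_raw = 100, seed = 1) {
  rows <- list()
  act <- .with_seed(seed * 131 + 17,
                    runif(max(1, nrow(cohort)), 0.6, 1.5))
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    scr <- if (is.null(script)) default_task_script(subj$affected_side) else
      script
    for (j in 1:2) {
      side <- c("left", "right")[j]
      sess <- simulate_session(subj, scr, side, fs_raw,
                               seed = (seed * 1009 + i * 31 + j) %% 2147483647,
                               activity_scale = act[i])
      role <- if (subj$group == "stroke") {
        if (side == subj$affected_side) "affected" else "unaffected"
      } else {
        if (side == subj$affected_side) "non-dominant" else "dominant"
      }
      rows[[length(rows) + 1L]] <- tibble(
        subject_id = subj$subject_id, group = subj$group,
        impairment = subj$impairment, fma = subj$fma,
        affected_side = subj$affected_side,
        side = side, side_role = role, raw = list(sess)
      )
    }
  }
  bind_rows(rows)
}
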