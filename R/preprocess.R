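#' Band-pass filter specification
#'
#' The signal-conditioning defaults used throughout the pipeline: a 4th-order
#' Butterworth band-pass between 0.1 and 12 Hz. The low edge removes the
#' quasi-static gravity component, the high edge removes frequencies above the
#' range of voluntary arm movement (roughly 10 Hz) before downsampling to
#' 25 Hz.
#'
#' @param low_hz Lower pass-band edge in Hz.
#' @param high_hz Upper pass-band edge in Hz.
#' @param order Butterworth prototype order of each (high-pass/low-pass) stage.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 12, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    abort("filter_spec requires 0 < low_hz < high_hz.")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

# Zero-phase IIR with edge handling suitable for near-DC poles: the series is
# linearly detrended (the high-pass would remove the trend anyway, this makes
# the constant/ramp part exact), extended by odd reflection about both
# endpoints, filtered forward-backward, and cropped. The reflection length is
# generous (10 s) because the 0.1 Hz pole has a multi-second impulse response.
.zero_phase <- function(flt, x, fs) {
  n <- length(x)
  x0 <- .lm.fit(cbind(1, seq_len(n)), x)$residuals
  pl <- min(n - 1L, as.integer(round(10 * fs)))
  xx <- c(2 * x0[1] - x0[seq(pl + 1L, 2L)], x0,
          2 * x0[n] - x0[seq(n - 1L, n - pl)])
  y <- signal::filtfilt(flt, xx)
  y[(pl + 1L):(pl + n)]
}

.design_stages <- function(spec, fs) {
  if (fs <= 2 * spec$high_hz) {
    abort(sprintf(
      "Sampling rate %g Hz violates Nyquist for the %g Hz filter edge.",
      fs, spec$high_hz))
  }
  list(hp = signal::butter(spec$order, spec$low_hz / (fs / 2), type = "high"),
       lp = signal::butter(spec$order, spec$high_hz / (fs / 2), type = "low"))
}

#' Zero-phase Butterworth band-pass of a multi-channel series
#'
#' Applies the band-pass as a cascade of a high-pass and a low-pass stage,
#' each run forward and backward (zero phase). Because of the double pass the
#' effective amplitude response is the squared single-pass Butterworth curve.
#'
#' @param x A data frame of numeric channels, a numeric matrix (samples x
#'   channels), or a numeric vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Same shape as the input, filtered per channel.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  min_len <- 3L * (2L * spec$order + 1L)
  if (nrow(m) <= min_len) {
    abort(sprintf("bandpass needs more than %d samples, got %d.",
                  min_len, nrow(m)))
  }
  stages <- .design_stages(spec, fs)
  out <- apply(m, 2, function(ch) {
    .zero_phase(stages$lp, .zero_phase(stages$hp, ch, fs), fs)
  })
  if (vec) return(as.numeric(out))
  if (is.data.frame(x)) {
    res <- as_tibble(as.data.frame(out))
    names(res) <- names(x)
    res
  } else {
    out
  }
}

#' Decimate a series to a lower sampling rate
#'
#' Keeps every `fs_in/fs_out`-th sample starting at the first one. Assumes the
#' series has already been low-passed below the target Nyquist (the 12 Hz edge
#' of [bandpass()] sits below 12.5 Hz), so no further anti-alias filter is
#' applied.
#'
#' @param x Data frame, matrix, or vector.
#' @param fs_in,fs_out Input/output sampling rates; `fs_in` must be an integer
#'   multiple of `fs_out`.
#' @return The decimated object, `ceiling(n / factor)` samples long.
#' @export
downsample <- function(x, fs_in, fs_out = 25) {
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf(
      "fs_in (%g) must be an integer multiple of fs_out (%g); resample first.",
      fs_in, fs_out))
  }
  factor <- as.integer(round(factor))
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  idx <- seq.int(1L, n, by = factor)
  if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
}

#' Estimate velocity from band-passed acceleration
#'
#' Cumulative trapezoidal integration per axis from a zero initial velocity,
#' followed by the same band-pass filter, which removes the integration drift.
#'
#' @param acc Tri-axial acceleration (data frame or matrix, samples x 3),
#'   already band-passed and at `fs`.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Velocity, same shape as `acc`, in m/s.
#' @export
integrate_velocity <- function(acc, fs, spec = filter_spec()) {
  m <- as.matrix(acc)
  if (ncol(m) != 3) abort("integrate_velocity expects 3 channels.")
  vel <- pracma::cumtrapz(seq_len(nrow(m)) / fs, m)
  out <- bandpass(vel, fs, spec)
  if (is.data.frame(acc)) {
    res <- as_tibble(as.data.frame(out))
    names(res) <- c("vx", "vy", "vz")
    res
  } else {
    out
  }
}

#' Condition a raw session into 25 Hz kinematics
#'
#' The full signal-conditioning chain for one wrist: band-pass the raw
#' tri-axial acceleration (removing gravity and high-frequency content),
#' decimate to 25 Hz, and estimate band-passed velocity by integration.
#' Sample labels are carried along by decimating the label track with the
#' signal.
#'
#' @param session A session tibble as produced by [simulate_session()], with
#'   columns `t, ax, ay, az, task_type, role` at `fs_raw`.
#' @param fs_raw Sampling rate of the input in Hz.
#' @param fs_out Target rate in Hz (default 25).
#' @param spec A [filter_spec()].
#' @return A kinematics tibble with columns
#'   `t, ax, ay, az, vx, vy, vz, task_type, role` at `fs_out`.
#' @export
preprocess_session <- function(session, fs_raw = 100, fs_out = 25,
                               spec = filter_spec()) {
  acc <- bandpass(session[, c("ax", "ay", "az")], fs_raw, spec)
  acc25 <- downsample(acc, fs_raw, fs_out)
  lab25 <- downsample(session[, c("task_type", "role")], fs_raw, fs_out)
  vel25 <- integrate_velocity(acc25, fs_out, spec)
  bind_cols(
    tibble(t = (seq_len(nrow(acc25)) - 1L) / fs_out),
    acc25, vel25, lab25
  )
}

#' Preprocess every session of a simulated cohort
#'
#' @param sessions A nested session tibble from [simulate_cohort()] (one row
#'   per subject and side, raw signal in the `raw` list-column).
#' @param fs_raw,fs_out,spec Passed to [preprocess_session()].
#' @return The input tibble with the `raw` column replaced by a `kinematics`
#'   list-column of 25 Hz acceleration + velocity tibbles.
#' @export
preprocess_cohort <- function(sessions, fs_raw = 100, fs_out = 25,
                              spec = filter_spec()) {
  sessions %>%
    mutate(kinematics = map(.data$raw, preprocess_session,
                            fs_raw = fs_raw, fs_out = fs_out, spec = spec)) %>%
    select(-"raw")
}
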