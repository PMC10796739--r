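#' Per-sample Euclidean magnitude of a tri-axial series
#'
#' @param x Matrix or data frame with exactly 3 numeric channels.
#' @return Numeric vector of per-sample norms.
#' @export
magnitude <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3) abort("magnitude expects exactly 3 channels.")
  sqrt(rowSums(m^2))
}

# Sign matrix with the zero-adoption convention: zeros inherit the previous
# nonzero sign (leading zeros inherit the next one), so same-sign runs are
# well defined. Columns are independent series.
.sign_fill <- function(m) {
  s <- sign(m)
  nr <- nrow(s)
  if (nr > 1) {
    for (i in 2:nr) {
      z <- s[i, ] == 0
      if (any(z)) s[i, z] <- s[i - 1L, z]
    }
    for (i in (nr - 1L):1L) {
      z <- s[i, ] == 0
      if (any(z)) s[i, z] <- s[i + 1L, z]
    }
  }
  s
}

#' Zero-crossing run lengths of a tri-axial series
#'
#' Splits each axis into maximal runs of equal sign. A sign change between
#' consecutive samples ends a run; zero samples adopt the neighbouring nonzero
#' sign (an all-zero axis is a single run spanning the series).
#'
#' @param x Matrix or data frame with 3 numeric channels, at least 2 samples.
#' @return A list of 3 integer vectors of run lengths (one per axis).
#' @export
crossing_segments <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3) abort("crossing_segments expects exactly 3 channels.")
  if (nrow(m) < 2) abort("crossing_segments needs at least 2 samples.")
  s <- .sign_fill(m)
  lapply(1:3, function(j) rle(s[, j])$lengths)
}

#' Summary statistics of zero-crossing runs
#'
#' @param segs A list of per-axis run-length vectors from
#'   [crossing_segments()].
#' @return A named list: `crossing_number` (sign changes summed over axes),
#'   `crossing_avg_length` (mean run length pooled over axes), and
#'   `crossing_entropy` (Shannon entropy, natural log, of the pooled empirical
#'   run-length distribution).
#' @export
crossing_stats <- function(segs) {
  if (length(segs) == 0) abort("crossing_stats needs a nonempty segment list.")
  lens <- unlist(segs)
  p <- tabulate(lens)
  p <- p[p > 0] / length(lens)
  list(
    crossing_number = sum(lengths(segs) - 1L),
    crossing_avg_length = mean(lens),
    crossing_entropy = -sum(p * log(p))
  )
}

#' Distributional and spectral statistics of a magnitude series
#'
#' @param mag Non-negative numeric vector (a magnitude series), length >= 8.
#' @param fs Sampling rate in Hz.
#' @return Named list with `min`, `max`, `median`, `rms`,
#'   `dom_freq_over_energy` (Hz of the periodogram peak, DC excluded, divided
#'   by the total periodogram sum), `skewness`, `kurtosis` (excess), and
#'   `entropy` (base-2 Shannon entropy of a 100-bin histogram of the values).
#'   Zero-variance input yields skewness, kurtosis and entropy of 0 by
#'   convention, and `dom_freq_over_energy` 0 when the non-DC spectrum is
#'   empty of energy.
#' @export
magnitude_stats <- function(mag, fs) {
  if (length(mag) < 8) {
    abort(sprintf("magnitude_stats needs at least 8 samples, got %d.",
                  length(mag)))
  }
  m <- matrix(as.numeric(mag), ncol = 1)
  as.list(.mag_stats_mat(m, fs)[1, ])
}

#' Pearson correlations between axis pairs
#'
#' @param x Matrix or data frame with 3 numeric channels.
#' @return Named list `corr_xy`, `corr_xz`, `corr_yz`; a pair involving a
#'   zero-variance axis is reported as 0.
#' @export
axis_correlations <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) != 3) abort("axis_correlations expects exactly 3 channels.")
  as.list(.corr_mat(m[, 1, drop = FALSE], m[, 2, drop = FALSE],
                    m[, 3, drop = FALSE])[1, ])
}

# ---- vectorized cores: each takes T x n matrices (n series of length T) ----

.corr_mat <- function(M1, M2, M3) {
  ctr <- function(M) sweep(M, 2, colMeans(M))
  C1 <- ctr(M1); C2 <- ctr(M2); C3 <- ctr(M3)
  ss1 <- colSums(C1^2); ss2 <- colSums(C2^2); ss3 <- colSums(C3^2)
  pair <- function(Ca, Cb, sa, sb) {
    den <- sqrt(sa * sb)
    ifelse(den > 0, colSums(Ca * Cb) / den, 0)
  }
  cbind(corr_xy = pair(C1, C2, ss1, ss2),
        corr_xz = pair(C1, C3, ss1, ss3),
        corr_yz = pair(C2, C3, ss2, ss3))
}

.crossing_mat <- function(M1, M2, M3) {
  nT <- nrow(M1); n <- ncol(M1)
  S <- lapply(list(M1, M2, M3), .sign_fill)
  cr <- lapply(S, function(s) colSums(s[-1, , drop = FALSE] *
                                        s[-nT, , drop = FALSE] < 0))
  total_cr <- cr[[1]] + cr[[2]] + cr[[3]]
  total_runs <- total_cr + 3
  ent <- numeric(n)
  for (w in seq_len(n)) {
    lens <- c(rle(S[[1]][, w])$lengths, rle(S[[2]][, w])$lengths,
              rle(S[[3]][, w])$lengths)
    p <- tabulate(lens)
    p <- p[p > 0] / length(lens)
    ent[w] <- -sum(p * log(p))
  }
  cbind(crossing_number = total_cr,
        crossing_avg_length = (3 * nT) / total_runs,
        crossing_entropy = ent)
}

.mag_stats_mat <- function(G, fs) {
  nT <- nrow(G); n <- ncol(G)
  mn <- do.call(pmin, c(asplit(G, 1), list(na.rm = FALSE)))
  mx <- do.call(pmax, c(asplit(G, 1), list(na.rm = FALSE)))
  med <- apply(G, 2, median)
  rms <- sqrt(colMeans(G^2))
  mu <- colMeans(G)
  D <- sweep(G, 2, mu)
  m2 <- colMeans(D^2); m3 <- colMeans(D^3); m4 <- colMeans(D^4)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  # plain FFT periodogram, DC bin excluded from the peak search
  P <- Mod(stats::mvfft(D))^2 / nT
  kmax <- floor(nT / 2)
  Ps <- P[seq_len(kmax) + 1L, , drop = FALSE]
  freqs <- seq_len(kmax) * fs / nT
  tot <- colSums(Ps)
  pk <- max.col(t(Ps), ties.method = "first")
  dfe <- ifelse(tot > 0, freqs[pk] / tot, 0)
  ent <- numeric(n)
  nb <- 100L
  for (w in seq_len(n)) {
    rng <- mx[w] - mn[w]
    if (rng <= 0) { ent[w] <- 0; next }
    b <- pmin(nb, floor(nb * (G[, w] - mn[w]) / rng) + 1L)
    p <- tabulate(b, nb)
    p <- p[p > 0] / nT
    ent[w] <- -sum(p * log2(p))
  }
  cbind(min = mn, max = mx, median = med, rms = rms,
        dom_freq_over_energy = dfe, skewness = skew, kurtosis = kurt,
        entropy = ent)
}

# Feature block for one signal given its three T x n channel matrices.
.signal_feature_mat <- function(M1, M2, M3, fs) {
  G <- sqrt(M1^2 + M2^2 + M3^2)
  cbind(.corr_mat(M1, M2, M3), .crossing_mat(M1, M2, M3),
        .mag_stats_mat(G, fs))
}

.feature_names_one <- c(
  "corr_xy", "corr_xz", "corr_yz",
  "crossing_number", "crossing_avg_length", "crossing_entropy",
  "min", "max", "median", "rms",
  "dom_freq_over_energy", "skewness", "kurtosis", "entropy"
)

#' Names of the 28 GDM descriptor features
#'
#' 14 statistics per signal (acceleration, velocity): three axis-pair
#' correlations, three zero-crossing run statistics, and eight magnitude
#' statistics.
#'
#' @return Character vector of length 28 (`acc_*` then `vel_*`).
#' @export
gdm_feature_names <- function() {
  c(paste0("acc_", .feature_names_one), paste0("vel_", .feature_names_one))
}

#' Extract the 28-feature GDM descriptor from one epoch
#'
#' @param acc,vel Tri-axial acceleration and velocity over the same samples
#'   (matrix or data frame, samples x 3), at least 8 samples.
#' @param fs Sampling rate in Hz.
#' @return A one-row tibble with the 28 columns of [gdm_feature_names()].
#' @export
extract_features <- function(acc, vel, fs) {
  ma <- as.matrix(acc); mv <- as.matrix(vel)
  if (ncol(ma) != 3 || ncol(mv) != 3) {
    abort("extract_features expects tri-axial acc and vel.")
  }
  if (nrow(ma) != nrow(mv)) {
    abort("acc and vel must cover the same samples.")
  }
  if (nrow(ma) < 8) abort("extract_features needs at least 8 samples.")
  one <- function(m) {
    .signal_feature_mat(m[, 1, drop = FALSE], m[, 2, drop = FALSE],
                        m[, 3, drop = FALSE], fs)
  }
  out <- cbind(one(ma), one(mv))
  colnames(out) <- gdm_feature_names()
  as_tibble(as.data.frame(out))
}

#' Extract the 28-feature descriptor for every window
#'
#' Vectorized across windows: all windows are reshaped into per-channel
#' matrices and each feature is computed for all windows at once. This is the
#' representation fed to the gradient-boosted detector backend.
#'
#' @param windows A windows tibble from [make_windows()] (optionally
#'   normalized with [apply_normalizer()]).
#' @param fs Sampling rate in Hz.
#' @return A numeric matrix, one row per window, 28 named columns.
#' @export
window_features <- function(windows, fs = 25) {
  mats <- .window_channel_mats(windows)
  .features_from_mats(mats, fs)
}

.features_from_mats <- function(mats, fs) {
  out <- cbind(
    .signal_feature_mat(mats[[1]], mats[[2]], mats[[3]], fs),
    .signal_feature_mat(mats[[4]], mats[[5]], mats[[6]], fs)
  )
  colnames(out) <- gdm_feature_names()
  out
}

# windows$data list-column -> list of 6 channel matrices (win_len x n_windows)
.window_channel_mats <- function(windows) {
  dat <- windows$data
  nT <- nrow(dat[[1]])
  lapply(1:6, function(ch) {
    vapply(dat, function(w) w[, ch], numeric(nT))
  })
}
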