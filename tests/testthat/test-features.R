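test_that("magnitude is the per-sample Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(0, 5, 3)), rep(0, 5))
  expect_equal(magnitude(cbind(rep(1, 4), 0, 0)), rep(1, 4))
  expect_error(magnitude(matrix(0, 5, 2)), "3 channels")
})

test_that("crossing segments match brute-force sign-change counting", {
  # 2 Hz cosine sampled at 25 Hz for 3 s
  x <- cos(2 * pi * 2 * (0:74) / 25)
  # oracle: count sign changes directly on the sampled sequence
  sgn <- sign(x)
  oracle_changes <- sum(sgn[-1] * sgn[-length(sgn)] < 0)
  segs <- crossing_segments(cbind(x, x, x))
  expect_equal(length(segs[[1]]) - 1, oracle_changes)
  expect_equal(oracle_changes, 12)
  expect_equal(length(segs[[1]]), 13)
  # strictly positive axis: one run, no crossings
  segs2 <- crossing_segments(cbind(abs(x) + 1, x, x))
  expect_equal(segs2[[1]], 75)
  # alternating signs: n runs of length 1
  alt <- rep(c(1, -1), length.out = 20)
  segs3 <- crossing_segments(cbind(alt, alt, alt))
  expect_equal(segs3[[1]], rep(1, 20))
  # run lengths always partition the series
  expect_true(all(vapply(segs, sum, numeric(1)) == 75))
})

test_that("crossing statistics pool axes with the stated conventions", {
  x <- cos(2 * pi * 2 * (0:74) / 25)
  st <- crossing_stats(crossing_segments(cbind(x, x, x)))
  expect_equal(st$crossing_number, 36)
  expect_equal(st$crossing_avg_length, 3 * 75 / 39)
  # degenerate distribution: zero entropy
  same <- crossing_stats(list(c(5, 5), c(5, 5), c(5)))
  expect_equal(same$crossing_entropy, 0)
  # two equally frequent lengths: ln 2
  two <- crossing_stats(list(c(2, 3), c(2, 3), c(2, 3)))
  expect_equal(two$crossing_entropy, log(2))
})

test_that("magnitude statistics follow the documented conventions", {
  const <- magnitude_stats(rep(3.5, 50), 25)
  expect_equal(const$min, 3.5)
  expect_equal(const$max, 3.5)
  expect_equal(const$median, 3.5)
  expect_equal(const$rms, 3.5)
  expect_equal(const$skewness, 0)
  expect_equal(const$kurtosis, 0)
  expect_equal(const$entropy, 0)
  expect_error(magnitude_stats(rep(1, 7), 25), "8 samples")

  # rectified 3 Hz sine peaks at 6 Hz; oracle: brute-force periodogram argmax
  fs <- 100
  x <- abs(sin(2 * pi * 3 * (0:999) / fs))
  xc <- x - mean(x)
  p <- Mod(fft(xc))^2
  k <- which.max(p[2:500]) # DC excluded
  expect_equal(k * fs / 1000, 6)
  st <- magnitude_stats(x, fs)
  # package convention: one-sided bins through Nyquist, scaled by 1/n
  expect_equal(st$dom_freq_over_energy, 6 / (sum(p[2:501]) / 1000),
               tolerance = 1e-9)

  # evenly spread values hit all 100 histogram bins: entropy log2(100)
  u <- seq(0, 1, length.out = 100)
  expect_equal(magnitude_stats(u, 25)$entropy, log2(100))
})

test_that("axis correlations handle exact and degenerate cases", {
  x <- rnorm(50)
  expect_equal(axis_correlations(cbind(x, x, rnorm(50)))$corr_xy, 1)
  expect_equal(axis_correlations(cbind(x, -x, rnorm(50)))$corr_xy, -1)
  expect_equal(axis_correlations(cbind(x, rep(1, 50), x))$corr_xy, 0)
  set.seed(11)
  big <- matrix(rnorm(30000), ncol = 3)
  expect_lt(abs(axis_correlations(big)$corr_xy), 0.1)
})

test_that("extract_features returns 28 named values with exact symmetries", {
  set.seed(5)
  acc <- matrix(rnorm(300), ncol = 3)
  vel <- matrix(rnorm(300), ncol = 3)
  f <- extract_features(acc, vel, 25)
  expect_equal(ncol(f), 28)
  expect_named(f, gdm_feature_names())
  # swapping acc and vel swaps the halves exactly
  g <- extract_features(vel, acc, 25)
  expect_equal(unname(as.numeric(g[1:14])), unname(as.numeric(f[15:28])))
  expect_equal(unname(as.numeric(g[15:28])), unname(as.numeric(f[1:14])))
  expect_error(extract_features(acc[1:50, ], vel, 25), "same samples")
})

test_that("features partition into scale-invariant and scale-equivariant", {
  set.seed(6)
  for (i in 1:5) {
    acc <- matrix(rnorm(225), ncol = 3)
    vel <- matrix(rnorm(225), ncol = 3)
    f1 <- extract_features(acc, vel, 25)
    f2 <- extract_features(2 * acc, 2 * vel, 25)
    invariant <- c("corr_xy", "corr_xz", "corr_yz", "crossing_number",
                   "crossing_avg_length", "crossing_entropy", "skewness",
                   "kurtosis", "entropy")
    equivariant <- c("min", "max", "median", "rms")
    for (pre in c("acc_", "vel_")) {
      for (nm in paste0(pre, invariant)) {
        expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-10)
      }
      for (nm in paste0(pre, equivariant)) {
        expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-10)
      }
    }
  }
})

test_that("run lengths always partition each axis of random signals", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    m <- matrix(rnorm(3 * n), ncol = 3)
    st <- crossing_stats(crossing_segments(m))
    total_runs <- st$crossing_number + 3
    expect_equal(st$crossing_avg_length * total_runs, 3 * n)
  }
})

test_that("all 28 features are finite on simulator output", {
  w <- mini_cohort()$windows
  x <- window_features(w)
  expect_true(all(is.finite(x)))
  expect_equal(ncol(x), 28)
  # the vectorized window path agrees with the single-epoch path
  i <- c(1, 10, 100)
  for (k in i) {
    f1 <- extract_features(w$data[[k]][, 1:3], w$data[[k]][, 4:6], 25)
    expect_equal(unname(x[k, ]), unname(as.numeric(f1[1, ])),
                 tolerance = 1e-12)
  }
})
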