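test_that("design construction z-scores and collapses columns", {
  set.seed(41)
  path <- sample.int(10, 500, replace = TRUE)
  ind <- state_indicators(path, 10)
  D <- build_design(ind)
  expect_equal(dim(D), c(500, 10))
  expect_lt(max(abs(colMeans(D))), 1e-8)
  expect_equal(apply(D, 2, sd), rep(1, 10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # four-into-one collapse gives a T x 7 design
  D7 <- build_design(ind, collapse = c(1, 4, 5, 7))
  expect_equal(ncol(D7), 7)
  expect_true("1+4+5+7" %in% attr(D7, "labels"))
  expect_error(build_design(ind, collapse = c(1, 11)), "outside")
})

test_that("partial correlations match the residualization oracle", {
  set.seed(42)
  T_len <- 200
  D <- matrix(rnorm(T_len * 3), T_len, 3)
  D[, 2] <- D[, 2] + 0.5 * D[, 1]    # correlated regressors matter here
  y <- 0.6 * D[, 1] - 0.3 * D[, 3] + rnorm(T_len)
  pm <- partial_correlation_map(D, matrix(y, ncol = 1))
  expect_equal(as.numeric(pm), pcor_residualization(D, y),
               tolerance = 1e-10)
})

test_that("maps recover planted per-channel modulation", {
  set.seed(43)
  T_len <- 4000
  path <- simulate_state_sequence(toy_chain(0.8), c(0.5, 0.5), T_len,
                                  seed = 44)
  env <- matrix(abs(rnorm(T_len * 4, mean = 1, sd = 0.3)), T_len, 4)
  env[path == 2, 3] <- env[path == 2, 3] * 2   # planted boost
  D <- build_design(state_indicators(path, 2))
  pm <- partial_correlation_map(D, env)
  expect_gt(pm[3, 2], 0.3)
  expect_equal(which.max(pm[, 2]), 3)
  # independent envelope gives near-zero coefficients
  expect_lt(max(abs(pm[c(1, 2, 4), ])), 3 / sqrt(T_len) * 3)
  # affine rescaling of the envelopes leaves coefficients unchanged
  pm2 <- partial_correlation_map(D, env * 7 + 2)
  expect_equal(unclass(pm2), unclass(pm), tolerance = 1e-10)
})

test_that("masked maps preserve the planted channel ranking", {
  set.seed(49)
  T_len <- 6000
  path <- simulate_state_sequence(toy_chain(0.85), c(0.5, 0.5), T_len,
                                  seed = 50)
  env <- matrix(abs(rnorm(T_len * 4, mean = 1, sd = 0.3)), T_len, 4)
  env[path == 1, 2] <- env[path == 1, 2] * 2
  rates <- occurrence_rate_timecourse(path, 2, fs = 20)
  mask <- high_rate_mask(rates, state = 1, T_len = T_len)
  D <- build_design(state_indicators(path, 2))
  pm <- partial_correlation_map(D, env, mask = mask)
  expect_gt(pm[2, 1], 0)
  expect_equal(which.max(pm[, 1]), 2)
})

test_that("band-specific maps are band-selective", {
  # alpha-modulated channel shows up in the alpha map, not the theta map
  fs <- 200
  T_raw <- 120 * fs
  path <- simulate_state_sequence(toy_chain(0.8), c(0.5, 0.5),
                                  120 * 20, seed = 45)
  gain <- 1 + (rep(path, each = 10) == 2)
  set.seed(46)
  mk_carrier <- function(lo, hi) {
    bf <- signal::butter(5, c(lo, hi) / (fs / 2), "pass")
    scale(signal::filtfilt(bf, rnorm(T_raw)))
  }
  x <- cbind(mk_carrier(8, 12) * gain + mk_carrier(4, 7),
             mk_carrier(8, 12), mk_carrier(4, 7))
  attr(x, "fs") <- fs
  envs <- lapply(list(theta = band_spec("theta"), alpha = band_spec("alpha")),
                 function(b) downsample_envelope(
                   hilbert_envelope(bandpass(x, b)), fs = fs, target_fs = 20))
  D <- build_design(state_indicators(path, 2))
  maps <- band_specific_maps(D, envs)
  expect_gt(maps$alpha[1, 2], 0.2)
  expect_lt(abs(maps$theta[1, 2]), 0.1)
})

test_that("map averaging handles signs as documented", {
  m1 <- matrix(c(0.5, -0.2), 2, 1)
  m2 <- matrix(c(-0.5, -0.2), 2, 1)
  expect_equal(unclass(average_maps(list(m1, m1))), m1, ignore_attr = TRUE)
  expect_equal(as.numeric(average_maps(list(m1, m2))), c(0, -0.2))
  # absolute averaging rectifies sign-ambiguous coefficients
  expect_equal(as.numeric(average_maps(list(m1, m2), use_absolute = TRUE)),
               c(0.5, 0.2))
  expect_error(average_maps(list(m1, matrix(0, 3, 1))), "shape")
})

test_that("ultra-slow rate maps find the coupled channel", {
  cfg <- synth_config(n_subjects = 1, duration_s = 540, K = 4,
                      n_channels = 8, occupancy = rep(0.25, 4),
                      self_trans = rep(0.75, 4),
                      ultraslow_gain = 0.9, ultraslow_hz = 0.05,
                      ultraslow_state = 2L, ultraslow_amp = 1, seed = 47)
  ch <- simulate_cohort(cfg)
  slow_raw <- lowpass_ultraslow(ch$raw[[1]], fs = 200)
  slow <- downsample_envelope(slow_raw, fs = 200, target_fs = 20)
  path <- ch$truth$paths[[1]]
  rates <- occurrence_rate_timecourse(path, 4, fs = 20)
  w <- attr(rates, "window_samples")
  slow_aligned <- slow[seq_len(nrow(rates)) + w %/% 2, ]
  pm <- ultraslow_rate_map(rates, slow_aligned)
  coupled_ch <- which(cfg$topographies[2, ] > 0)
  # strongest coupling sits in the planted (channel, state) block
  peak <- arrayInd(which.max(abs(pm)), dim(pm))
  expect_true(peak[1] %in% coupled_ch)
  expect_equal(peak[2], 2L, ignore_attr = TRUE)
  # sign-flipping the slow signal leaves the absolute map unchanged
  pm_flip <- ultraslow_rate_map(rates, -slow_aligned)
  expect_equal(abs(unclass(pm_flip)), abs(unclass(pm)), tolerance = 1e-10)
})

test_that("session-average amplitude obeys the law of total expectation", {
  set.seed(48)
  path <- sample.int(2, 1000, replace = TRUE)
  env <- matrix(abs(rnorm(2000)), 1000, 2)
  tab <- session_average_amplitude(list(wide = env))
  expect_equal(tab$amplitude, colMeans(env))
  fo <- fractional_occupancy(path, 2)
  per_state <- sapply(1:2, function(k) colMeans(env[path == k, ]))
  expect_equal(as.numeric(per_state %*% fo), colMeans(env),
               tolerance = 1e-12)
  # two equal halves average to the midpoint
  e2 <- matrix(c(rep(2, 500), rep(4, 500)), ncol = 1)
  expect_equal(session_average_amplitude(list(b = e2))$amplitude, 3)
})
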