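test_that("state sequences follow the planted chain", {
  # absorbing chain stays put
  A <- diag(2)
  expect_equal(simulate_state_sequence(A, c(1, 0), 50, seed = 1),
               rep(1L, 50))
  # symmetric two-state chain spends half its time in each state
  p <- simulate_state_sequence(toy_chain(0.8), c(0.5, 0.5), 1e5, seed = 2)
  expect_equal(unname(fractional_occupancy(p, 2)), c(0.5, 0.5),
               tolerance = 0.02)
  # geometric dwell: self-transition 0.8 gives mean dwell 1/(1-0.8) = 5
  p2 <- simulate_state_sequence(toy_chain(0.8), c(0.5, 0.5), 2e5, seed = 3)
  expect_equal(mean(rle(p2)$lengths), 5, tolerance = 0.03)
  # reproducible under a fixed seed
  expect_identical(p, simulate_state_sequence(toy_chain(0.8), c(0.5, 0.5),
                                              1e5, seed = 2))
  expect_error(simulate_state_sequence(matrix(1, 2, 2), c(0.5, 0.5), 10),
               "sum to 1")
})

test_that("transition_from_occupancy plants occupancy and dwell exactly", {
  occ <- c(0.06, rep(0.1, 4), 0.14, rep(0.1, 4))
  st <- c(0.8, rep(2 / 3, 4), 0.75, rep(2 / 3, 4))
  A <- transition_from_occupancy(occ, st)
  expect_equal(rowSums(A), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(diag(A)), st, tolerance = 1e-12)
  expect_equal(stationary_distribution(A), occ, tolerance = 1e-9)
})

test_that("cohort generation is shaped, grounded, and deterministic", {
  cfg <- tiny_cohort()
  ch <- simulate_cohort(cfg)
  expect_length(ch$raw, 2)
  expect_equal(dim(ch$raw[[1]]), c(90 * 200, 9))
  # ground-truth paths live at the envelope rate
  expect_length(ch$truth$paths[[1]], 90 * 20)
  expect_true(all(ch$truth$paths[[1]] %in% 1:3))
  # bitwise determinism under identical config
  ch2 <- simulate_cohort(tiny_cohort())
  expect_identical(ch$raw, ch2$raw)
  expect_identical(ch$truth$paths, ch2$truth$paths)
  expect_error(synth_config(duration_s = -1), "duration")
  expect_error(synth_config(n_channels = 0), "n_channels")
})

test_that("planted modulation raises the active channels' envelope", {
  cfg <- tiny_cohort(n_subjects = 1, duration_s = 120, seed = 9)
  ch <- simulate_cohort(cfg)
  x <- ch$raw[[1]]
  env <- downsample_envelope(hilbert_envelope(x), fs = 200, target_fs = 20)
  path <- ch$truth$paths[[1]]
  chans <- which(cfg$topographies[1, ] > 0)
  inside <- colMeans(env[path == 1, chans, drop = FALSE])
  outside <- colMeans(env[path != 1, chans, drop = FALSE])
  # paired per-channel contrast: all active channels are louder in-state
  expect_true(all(inside > outside))
  # depth 0 plants nothing
  cfg0 <- tiny_cohort(n_subjects = 1, duration_s = 120, seed = 9, depth = 0)
  ch0 <- simulate_cohort(cfg0)
  env0 <- downsample_envelope(hilbert_envelope(ch0$raw[[1]]), fs = 200,
                              target_fs = 20)
  d0 <- colMeans(env0[path == 1, chans, drop = FALSE]) -
    colMeans(env0[path != 1, chans, drop = FALSE])
  expect_lt(max(abs(d0)), 0.2)
})

test_that("ultra-slow coupling modulates the state occurrence rate", {
  cfg <- synth_config(n_subjects = 1, duration_s = 540, K = 4,
                      n_channels = 8, occupancy = rep(0.25, 4),
                      self_trans = rep(0.75, 4),
                      ultraslow_gain = 0.9, ultraslow_hz = 0.05, seed = 5)
  mod <- simulate_ultraslow_modulation(cfg)
  T_env <- 540 * 20
  expect_length(mod$modulator, T_env)
  # 0.05 Hz modulator has a 20 s period
  expect_equal(mod$modulator[1], mod$modulator[1 + 20 * 20])
  A <- transition_from_occupancy(cfg$occupancy, cfg$self_trans)
  path <- simulate_state_sequence(A, rep(0.25, 4), T_env, seed = 6,
                                  entry_scale = mod$entry_scale,
                                  coupled_state = 1L)
  rate <- occurrence_rate_timecourse(path, 4, fs = 20)[, 1]
  m_align <- mod$modulator[seq_along(rate) + attr(
    occurrence_rate_timecourse(path, 4, fs = 20), "window_samples") %/% 2]
  expect_gt(cor(rate, m_align), 0.5)
  # gain 0: no coupling
  path0 <- simulate_state_sequence(A, rep(0.25, 4), 1e4, seed = 6)
  rate0 <- occurrence_rate_timecourse(path0, 4, fs = 20)[, 1]
  expect_lt(abs(cor(rate0, mod$modulator[seq_along(rate0)])), 0.1)
  # excessive gain errors
  expect_error(synth_config(
    n_subjects = 1, duration_s = 10, K = 2, n_channels = 4,
    occupancy = c(.5, .5), self_trans = c(.5, .5), ultraslow_gain = 1.5),
    "gain")
})

test_that("surrogates match spectra and zero-lag correlations", {
  set.seed(11)
  # correlated 3-channel reference with band-limited structure
  n <- 1e5
  z <- matrix(rnorm(n * 3), n, 3)
  mix <- matrix(c(1, .6, .3, 0, .8, .5, 0, 0, .8), 3)
  ref <- z %*% mix
  attr(ref, "fs") <- 200
  sur <- simulate_surrogate(ref, n_datasets = 3, seed = 21)
  expect_length(sur, 3)
  expect_false(identical(sur[[1]], sur[[2]]))
  expect_lt(max(abs(cor(sur[[1]]) - cor(ref))), 0.05)
  # white-noise reference gives near-flat surrogate spectra in 4-30 Hz
  wn <- matrix(rnorm(2e4 * 2), 2e4, 2)
  sw <- simulate_surrogate(wn, 1, seed = 3)[[1]]
  sp <- Mod(fft(sw[, 1]))^2
  f <- (seq_len(2e4) - 1) * 200 / 2e4
  band <- f >= 4 & f <= 30
  bp <- tapply(sp[band], cut(f[band], 6), mean)
  expect_lt(max(bp) / min(bp), 1.5)
  # rank-deficient reference is rejected with a rank report
  bad <- cbind(ref[, 1], ref[, 1], ref[, 2])
  expect_error(simulate_surrogate(bad, 1), "rank")
})

test_that("surrogate spectra track a colored reference", {
  cfg <- tiny_cohort(n_subjects = 1, duration_s = 60, seed = 31)
  ref <- simulate_cohort(cfg)$raw[[1]][, 1:3]
  attr(ref, "fs") <- 200
  sur <- simulate_surrogate(ref, 1, seed = 4)[[1]]
  # band-limited reference: surrogate keeps most power inside 4-30 Hz
  sp <- Mod(fft(sur[, 1]))^2
  n <- nrow(ref)
  f <- (seq_len(n) - 1) * 200 / n
  half <- f <= 100
  inband <- f >= 3 & f <= 31
  expect_gt(sum(sp[half & inband]) / sum(sp[half]), 0.9)
})
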