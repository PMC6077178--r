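fs <- 200
tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
mid <- seq(5 * fs, 55 * fs)  # away from filter edges

test_that("band-pass filter passes the band and rejects the rest", {
  x10 <- sin(2 * pi * 10 * tt)
  y <- bandpass(x10, band_spec("alpha"), fs = fs)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.05)
  y2 <- bandpass(x10, band_spec("beta"), fs = fs)
  expect_lt(sqrt(mean(y2[mid]^2)), 0.1)
  # DC is excluded from the wide band
  ydc <- bandpass(rep(1, length(tt)), band_spec("wide"), fs = fs)
  expect_lt(max(abs(ydc[mid])), 1e-6)
  expect_error(bandpass(x10, band_spec(low = 4, high = 150), fs = fs),
               "Nyquist")
})

test_that("ultra-slow lowpass keeps <0.1 Hz and rejects 1 Hz", {
  t2 <- seq(0, 200 - 1 / fs, by = 1 / fs)
  mid2 <- seq(40 * fs, 160 * fs)
  y <- lowpass_ultraslow(sin(2 * pi * 0.05 * t2), fs = fs)
  expect_equal(max(abs(y[mid2])), 1, tolerance = 0.1)
  y1 <- lowpass_ultraslow(sin(2 * pi * 1 * t2), fs = fs)
  expect_lt(sqrt(mean(y1[mid2]^2)), 0.1)
  expect_equal(lowpass_ultraslow(numeric(length(t2)) , fs = fs),
               numeric(length(t2)), ignore_attr = TRUE)
})

test_that("first-PC region time-course recovers planted structure", {
  set.seed(4)
  # single voxel: returns the centered series
  v <- rnorm(100)
  expect_equal(extract_roi_timecourse(matrix(v, ncol = 1)),
               v - mean(v), tolerance = 1e-10)
  # two identical voxels: rank one, perfect reconstruction
  v2 <- cbind(v, v)
  tc <- extract_roi_timecourse(v2)
  expect_equal(abs(cor(tc, v)), 1, tolerance = 1e-10)
  # planted rank-1 structure recovered under noise
  s <- sin(2 * pi * (1:500) / 50)
  w <- c(2, -1, 0.5, 1.5)
  vox <- outer(s, w) + matrix(rnorm(2000, sd = 0.3), 500, 4)
  rec <- extract_roi_timecourse(vox)
  expect_gt(abs(cor(rec, s)), 0.95)
  expect_error(extract_roi_timecourse(matrix(0, 10, 2)), "zero")
})

test_that("symmetric orthogonalization is a least-squares projection", {
  set.seed(7)
  # fixed point on already-orthogonal input
  Q <- qr.Q(qr(matrix(rnorm(200 * 3), 200, 3))) %*% diag(c(2, 1, 3))
  expect_equal(symmetric_orthogonalize(Q), Q, tolerance = 1e-8,
               ignore_attr = TRUE)
  # output columns are pairwise orthogonal
  X <- matrix(rnorm(500 * 3), 500, 3)
  X[, 2] <- X[, 2] + 0.8 * X[, 1]
  Xo <- symmetric_orthogonalize(X)
  G <- crossprod(Xo)
  ncor <- abs(G[upper.tri(G)]) /
    (sqrt(diag(G)) %o% sqrt(diag(G)))[upper.tri(G)]
  expect_lt(max(ncor), 1e-8)
  # beats every sequential Gram-Schmidt column ordering in displacement
  gs <- function(X, ord) {
    Y <- X[, ord, drop = FALSE]
    for (j in 2:ncol(Y)) {
      prev <- Y[, 1:(j - 1), drop = FALSE]
      Y[, j] <- Y[, j] - prev %*% solve(crossprod(prev), crossprod(prev, Y[, j]))
    }
    Y[, order(ord)]
  }
  d_sym <- norm(X - Xo, "F")
  library(utils)
  for (ord in asplit(rbind(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
    c(3, 2, 1)), 1)) {
    expect_lte(d_sym, norm(X - gs(X, ord), "F") + 1e-10)
  }
  # identical columns are rejected with the offending columns named
  expect_error(symmetric_orthogonalize(cbind(X[, 1], X[, 1], X[, 2])),
               "rank deficient")
})

test_that("orthogonalization is invariant to column reordering", {
  set.seed(8)
  X <- matrix(rnorm(400 * 4), 400, 4)
  X[, 3] <- X[, 3] + 0.5 * X[, 2]
  Xo <- symmetric_orthogonalize(X)
  perm <- c(3, 1, 4, 2)
  Xo_p <- symmetric_orthogonalize(X[, perm])[, order(perm)]
  expect_equal(Xo, Xo_p, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Hilbert envelope demodulates amplitude", {
  x <- 2.5 * sin(2 * pi * 10 * tt)
  e <- hilbert_envelope(x)
  expect_equal(mean(e[mid]), 2.5, tolerance = 0.02)
  expect_true(all(e >= 0))
  expect_equal(hilbert_envelope(numeric(100)), numeric(100),
               ignore_attr = TRUE)
  # AM carrier: envelope tracks the modulator
  modu <- 1 + 0.5 * sin(2 * pi * 0.5 * tt)
  e2 <- hilbert_envelope(modu * sin(2 * pi * 10 * tt))
  expect_gt(cor(e2[mid], modu[mid]), 0.98)
})

test_that("block-mean downsampling averages exact windows", {
  e <- matrix(rep(c(0, 2), 50), ncol = 1)
  expect_equal(as.numeric(downsample_envelope(e, fs = 200, target_fs = 20)),
               rep(1, 10))
  cst <- matrix(3.3, 36000, 2)
  d <- downsample_envelope(cst, fs = 200, target_fs = 20)
  expect_equal(dim(d), c(3600, 2))
  expect_true(all(d == 3.3))
  expect_error(downsample_envelope(cst, fs = 200, target_fs = 30),
               "multiple")
})

test_that("normalization demeans per channel and scales globally", {
  set.seed(9)
  e1 <- matrix(rnorm(600, mean = 5), 200, 3)
  e2 <- matrix(rnorm(300, mean = 2, sd = 4), 100, 3)
  cc <- normalize_concatenate(list(e1, e2), fs = 20)
  expect_equal(dim(cc$values), c(300, 3))
  expect_equal(cc$boundaries, c(1L, 201L))
  sub1 <- cc$values[1:200, ]
  expect_lt(max(abs(colMeans(sub1))), 1e-12)
  expect_equal(sd(as.numeric(sub1)), 1, tolerance = 1e-12)
  # scale invariance: scaling one subject leaves its normalized block alone
  cc10 <- normalize_concatenate(list(e1 * 10, e2), fs = 20)
  expect_equal(cc10$values, cc$values, tolerance = 1e-12)
  expect_error(normalize_concatenate(list(e1, e2[, 1:2])), "channel")
})

test_that("envelopes of planted-state channels rise during visits", {
  cfg <- tiny_cohort(n_subjects = 1, duration_s = 120, seed = 12)
  ch <- simulate_cohort(cfg)
  env <- prepare_envelopes(ch$raw)
  trim <- attr(env, "trim_samples")
  path <- ch$truth$paths[[1]]
  path <- path[(trim + 1):(length(path) - trim)]
  chans <- which(cfg$topographies[2, ] > 0)
  diffs <- colMeans(env$values[path == 2, chans, drop = FALSE]) -
    colMeans(env$values[path != 2, chans, drop = FALSE])
  expect_true(all(diffs > 0))
})
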