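#' Frequency band presets
#'
#' Standard analysis bands: `wide` (4-30 Hz), `theta` (4-7 Hz), `alpha`
#' (8-12 Hz), `beta` (15-30 Hz), and `ultraslow` (lowpass below 0.1 Hz).
#'
#' @param name Band name, or `NULL` to construct a custom band.
#' @param low,high Custom band edges in Hz; for a lowpass band set
#'   `low = 0`.
#' @return A `band_spec` list with `name`, `low`, `high`.
#' @export
band_spec <- function(name = NULL, low = NULL, high = NULL) {
  presets <- list(wide = c(4, 30), theta = c(4, 7), alpha = c(8, 12),
                  beta = c(15, 30), ultraslow = c(0, 0.1))
  if (!is.null(name) && is.null(low)) {
    name <- match.arg(name, names(presets))
    low <- presets[[name]][1]; high <- presets[[name]][2]
  }
  if (is.null(name)) name <- sprintf("band_%g_%g", low, high)
  if (low < 0 || high <= low) stopf("need 0 <= low < high")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Zero-phase band-pass filter
#'
#' Filters every channel of a time x channels matrix into `band` with a
#' forward-backward (zero-phase) Butterworth filter of order 5 per pass.
#'
#' @param x `T x M` numeric matrix (or vector) with an `fs` attribute, or
#'   supply `fs` explicitly.
#' @param band A [band_spec()]; `low = 0` selects a lowpass response.
#' @param fs Sampling rate in Hz (overrides `attr(x, "fs")`).
#' @return Filtered matrix, same shape, `fs` attribute preserved.
#' @export
bandpass <- function(x, band, fs = attr(x, "fs")) {
  if (is.null(fs)) stopf("sampling rate fs is required")
  if (!inherits(band, "band_spec")) stopf("band must be a band_spec")
  if (band$high >= fs / 2)
    stopf("band edge %g Hz is at or beyond Nyquist (%g Hz)",
          band$high, fs / 2)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  if (!all(is.finite(x))) stopf("input contains non-finite values")
  bf <- if (band$low <= 0) {
    signal::butter(5, band$high / (fs / 2), type = "low")
  } else {
    signal::butter(5, c(band$low, band$high) / (fs / 2), type = "pass")
  }
  y <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  y <- matrix(y, nrow = nrow(x))
  if (vec) y <- y[, 1]
  attr(y, "fs") <- fs
  y
}

#' Ultra-slow lowpass filter
#'
#' Zero-phase lowpass at `cutoff` Hz (default 0.1 Hz), used to extract the
#' ultra-slow potential fluctuations whose coupling to state occurrence
#' rates is mapped downstream.
#'
#' @inheritParams bandpass
#' @param cutoff Lowpass cutoff in Hz.
#' @export
lowpass_ultraslow <- function(x, fs = attr(x, "fs"), cutoff = 0.1) {
  bandpass(x, band_spec("ultraslow", low = 0, high = cutoff), fs = fs)
}

#' First-principal-component region time-course
#'
#' Collapses a time x voxels matrix to one representative time-course: the
#' scores of the first principal component, with the spatial loading
#' sign-fixed so its positive peak is +1, scaled by the supplied spatial
#' map strength.
#'
#' @param voxels `T x V` matrix of voxel time-courses.
#' @param weights Length-`V` spatial map used only for its maximum strength
#'   scaling (default all ones).
#' @return Length-`T` numeric time-course.
#' @export
extract_roi_timecourse <- function(voxels, weights = NULL) {
  if (!is.matrix(voxels)) voxels <- matrix(voxels, ncol = 1)
  if (all(voxels == 0)) stopf("all-zero input")
  weights <- weights %||% rep(1, ncol(voxels))
  if (length(weights) != ncol(voxels))
    stopf("weights must have one entry per voxel")
  xc <- sweep(voxels, 2, colMeans(voxels))
  sv <- svd(xc, nu = 1, nv = 1)
  loading <- sv$v[, 1]
  peak <- loading[which.max(abs(loading))]
  loading <- loading / peak          # positive peak at +1
  tc <- xc %*% loading
  as.numeric(tc * max(abs(weights)))
}

#' Symmetric (all-at-once) orthogonalization
#'
#' Removes zero-lag signal leakage by replacing the columns of `X` with the
#' closest set of mutually orthogonal time-courses in the least-squares
#' sense: the minimizer of the Frobenius distance to `X` over matrices of
#' the form `L diag(rho)` with orthonormal `L`. Solved by alternating the
#' closest-orthonormal-matrix (SVD polar) step with per-column magnitude
#' updates. The result is invariant to column reordering, unlike sequential
#' Gram-Schmidt.
#'
#' @param X `T x M` matrix, `T >= M`, full column rank.
#' @param tol Relative objective change declaring convergence.
#' @param max_iter Iteration cap.
#' @return `T x M` matrix with pairwise-orthogonal columns; attribute
#'   `iterations` records the count.
#' @export
symmetric_orthogonalize <- function(X, tol = 1e-10, max_iter = 1000) {
  if (!is.matrix(X) || nrow(X) < ncol(X))
    stopf("X must be a T x M matrix with T >= M")
  M <- ncol(X)
  qrX <- qr(X, LAPACK = TRUE)
  d <- abs(diag(qr.R(qrX)))
  rank <- sum(d > 1e-10 * max(d))
  if (rank < M)
    stopf("X is rank deficient (rank %d of %d); offending columns: %s",
          rank, M, paste(sort(qrX$pivot[(rank + 1):M]), collapse = ", "))
  # work in the M x M coefficient space of X = Q R
  qrU <- qr(X)                   # unpivoted thin factorization
  Q <- qr.Q(qrU)
  R <- qr.R(qrU)
  rho <- sqrt(colSums(X^2))
  obj_old <- Inf
  total <- sum(X^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sv <- svd(R %*% diag(rho, M))
    O <- sv$u %*% t(sv$v)        # polar factor: closest orthonormal basis
    rho <- diag(t(O) %*% R)      # optimal per-column magnitudes
    obj <- total - sum(rho^2)    # ||X - Q O diag(rho)||_F^2
    if (is.finite(obj_old) &&
        abs(obj_old - obj) <= tol * max(abs(obj_old), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged)
    stopf("orthogonalization did not converge in %d iterations (last objective change %.3g)",
          max_iter, abs(obj_old - obj))
  out <- Q %*% O %*% diag(rho, M)
  dimnames(out) <- dimnames(X)
  attr(out, "fs") <- attr(X, "fs")
  attr(out, "iterations") <- it
  out
}

#' Hilbert amplitude envelope
#'
#' Instantaneous amplitude of each channel, computed as the modulus of the
#' analytic signal (FFT construction).
#'
#' @param x `T x M` matrix or vector, finite.
#' @return Nonnegative envelope of the same shape; `fs` preserved.
#' @export
hilbert_envelope <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  if (!all(is.finite(x))) stopf("input contains non-finite values")
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
  if (vec) env <- env[, 1] else env <- matrix(env, nrow = n)
  attr(env, "fs") <- attr(x, "fs")
  env
}

#' Downsample an envelope by block averaging
#'
#' Averages consecutive non-overlapping windows of `fs / target_fs`
#' samples, anti-aliasing the envelope while reducing the rate.
#'
#' @param e `T x M` envelope matrix (or vector) at rate `fs`.
#' @param fs Input rate in Hz.
#' @param target_fs Output rate in Hz; must divide `fs`.
#' @return Envelope at `target_fs`, length `floor(T * target_fs / fs)`.
#' @export
downsample_envelope <- function(e, fs = attr(e, "fs"), target_fs = 20) {
  if (is.null(fs)) stopf("sampling rate fs is required")
  if (fs %% target_fs != 0)
    stopf("fs (%g) must be an integer multiple of target_fs (%g)",
          fs, target_fs)
  vec <- !is.matrix(e)
  if (vec) e <- matrix(e, ncol = 1)
  r <- fs %/% target_fs
  T_out <- nrow(e) %/% r
  idx <- seq_len(T_out * r)
  out <- apply(e[idx, , drop = FALSE], 2, function(col)
    colMeans(matrix(col, nrow = r)))
  out <- matrix(out, nrow = T_out)
  dimnames(out) <- list(NULL, colnames(e))
  if (vec) out <- out[, 1]
  attr(out, "fs") <- target_fs
  out
}

#' Demean, scale, and concatenate subject envelopes
#'
#' Per subject, each channel is demeaned and the whole subject matrix is
#' divided by its global (all channels pooled) standard deviation; subjects
#' are then stacked in time with recorded boundaries. This is the input the
#' HMM is fitted on.
#'
#' @param envelopes List of `T_s x M` envelope matrices sharing `M` and
#'   sampling rate.
#' @param fs Envelope rate in Hz (taken from the first element's attribute
#'   if present).
#' @return An `env_concat` object: list with `values` (stacked matrix),
#'   `fs`, `boundaries` (first row index of each subject), `lengths`.
#' @export
normalize_concatenate <- function(envelopes,
                                  fs = attr(envelopes[[1]], "fs")) {
  if (!length(envelopes)) stopf("no envelopes supplied")
  M <- ncol(envelopes[[1]])
  if (!all(vapply(envelopes, ncol, 0L) == M))
    stopf("all subjects must share the channel count")
  normed <- lapply(envelopes, function(e) {
    e <- sweep(e, 2, colMeans(e))
    e / sd(as.numeric(e))
  })
  lens <- vapply(normed, nrow, 0L)
  structure(list(values = do.call(rbind, normed), fs = fs,
                 boundaries = cumsum(c(1L, head(lens, -1L))),
                 lengths = lens),
            class = "env_concat")
}

#' Split a concatenated matrix back into per-subject blocks
#'
#' @param x An `env_concat`, or a matrix whose rows follow `lengths`.
#' @param lengths Per-subject row counts (taken from `x` if `env_concat`).
#' @return List of per-subject matrices.
#' @export
split_subjects <- function(x, lengths = NULL) {
  if (inherits(x, "env_concat")) {
    lengths <- x$lengths
    x <- x$values
  }
  if (is.null(lengths)) stopf("lengths required for a bare matrix")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  lapply(seq_along(lengths), function(s)
    x[starts[s]:ends[s], , drop = FALSE])
}

#' Raw cohort to concatenated envelopes
#'
#' The standard preprocessing chain: band-pass filter each subject into
#' `band`, optionally leakage-correct by symmetric orthogonalization,
#' compute Hilbert envelopes, block-average down to `target_fs`, discard
#' `trim_s` seconds at both ends (filter/Hilbert transients), then demean,
#' scale, and concatenate across subjects.
#'
#' @param raw List of per-subject `T x M` raw matrices with `fs` attributes.
#' @param band A [band_spec()] (default wide 4-30 Hz).
#' @param orthogonalize Apply symmetric orthogonalization before envelope
#'   computation (leakage correction), default `TRUE`.
#' @param target_fs Envelope rate (Hz).
#' @param trim_s Seconds discarded at each end of every subject's envelope.
#' @return An `env_concat` (see [normalize_concatenate()]); attribute
#'   `trim_samples` records the per-end sample trim at `target_fs`.
#' @export
prepare_envelopes <- function(raw, band = band_spec("wide"),
                              orthogonalize = TRUE, target_fs = 20,
                              trim_s = 1) {
  envs <- lapply(raw, function(x) {
    fs <- attr(x, "fs")
    xb <- bandpass(x, band, fs = fs)
    if (orthogonalize) xb <- symmetric_orthogonalize(xb)
    attr(xb, "fs") <- fs
    e <- hilbert_envelope(xb)
    e <- downsample_envelope(e, fs = fs, target_fs = target_fs)
    trim <- round(trim_s * target_fs)
    if (nrow(e) <= 2 * trim) stopf("recording shorter than the edge trim")
    e[(trim + 1):(nrow(e) - trim), , drop = FALSE]
  })
  out <- normalize_concatenate(envs, fs = target_fs)
  attr(out, "trim_samples") <- round(trim_s * target_fs)
  out
}
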