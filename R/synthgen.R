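#' Configure a synthetic cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' generator emulates resting-state source-space recordings in which a latent
#' K-state Markov chain switches between network states, each state raising
#' the oscillatory amplitude of its own set of channels. Two presets encode
#' the cohort contrasts the package is validated against: `"ch_default"`
#' (healthy-control-like) plants fractional occupancies of 6% for the
#' DMN-like state and 14% for the DAN-like state with mean dwell times of
#' 250 ms and 200 ms, while `"ad_default"` (Alzheimer-like) halves those
#' occupancies (3% / 7%), shortens both dwell times to 150 ms, and attenuates
#' the DMN-like modulation depth.
#'
#' State dynamics are generated at the envelope rate (`fs_env`, 20 Hz) and
#' sample-held up to `fs_raw` before amplitude modulation, so ground-truth
#' paths align sample-for-sample with decoded paths.
#'
#' @param preset `"ch_default"`, `"ad_default"`, or `NULL` for fully manual
#'   configuration.
#' @param n_subjects Subjects in the cohort.
#' @param duration_s Recording length per subject in seconds (default 540 s,
#'   i.e. three concatenated 3-minute runs).
#' @param fs_raw Raw sampling rate in Hz.
#' @param fs_env Envelope rate in Hz; must divide `fs_raw`.
#' @param n_channels Number of channels / regions (default 38).
#' @param K Number of latent states.
#' @param occupancy Length-`K` stationary occupancy targets (sums to 1).
#' @param self_trans Length-`K` self-transition probabilities in `[0, 1)`;
#'   mean dwell of state k is `1 / (1 - self_trans[k])` envelope samples.
#' @param topographies `K x n_channels` nonnegative modulation map; row k
#'   scales channel amplitudes by `1 + depth * state_depth[k] *
#'   topographies[k, m]` while state k is active.
#' @param depth Global modulation depth multiplier.
#' @param state_depth Optional per-state depth multipliers (length `K`).
#' @param leakage `n_channels x n_channels` zero-lag mixing matrix applied
#'   after modulation (`NULL` = identity = no leakage).
#' @param noise_sd Carrier standard deviation before modulation.
#' @param ultraslow_hz Frequency of the ultra-slow modulator (< 0.1 Hz).
#' @param ultraslow_gain Coupling gain scaling the probability of entering
#'   the coupled state by `1 + gain * modulator(t)`; 0 disables coupling.
#' @param ultraslow_state Index of the state coupled to the modulator.
#' @param ultraslow_amp Amplitude of the slow potential added to the coupled
#'   state's channels (signal units).
#' @param group Group label attached to the cohort.
#' @param seed Integer seed; every stochastic stage derives sub-seeds from it.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(preset = NULL,
                         n_subjects = 10, duration_s = 540,
                         fs_raw = 200, fs_env = 20,
                         n_channels = 38, K = 10,
                         occupancy = NULL, self_trans = NULL,
                         topographies = NULL,
                         depth = 1, state_depth = NULL,
                         leakage = NULL, noise_sd = 1,
                         ultraslow_hz = 0.05, ultraslow_gain = 0,
                         ultraslow_state = 1L, ultraslow_amp = 0.5,
                         group = preset %||% "synthetic",
                         seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("ch_default", "ad_default"))
    if (K < 6)
      stopf("cohort presets place the DMN-like state at 1 and the DAN-like state at 6; K must be >= 6")
    # State 1 is the DMN-like state, state 6 the DAN-like state; remaining
    # states share the residual occupancy with ~150 ms dwell times.
    if (preset == "ch_default") {
      occupancy <- occupancy %||% {
        occ <- rep((1 - 0.06 - 0.14) / (K - 2), K)
        occ[1] <- 0.06; occ[6] <- 0.14
        occ
      }
      self_trans <- self_trans %||% {
        st <- rep(2 / 3, K)           # 150 ms at 20 Hz
        st[1] <- 1 - 1 / (fs_env * 0.250)   # 250 ms
        st[6] <- 1 - 1 / (fs_env * 0.200)   # 200 ms
        st
      }
    } else {
      occupancy <- occupancy %||% {
        occ <- rep((1 - 0.03 - 0.07) / (K - 2), K)
        occ[1] <- 0.03; occ[6] <- 0.07
        occ
      }
      self_trans <- self_trans %||% rep(2 / 3, K)  # all ~150 ms
      state_depth <- state_depth %||% {
        d <- rep(1, K); d[1] <- 0.7; d
      }
    }
  }
  occupancy <- occupancy %||% rep(1 / K, K)
  self_trans <- self_trans %||% rep(2 / 3, K)
  state_depth <- state_depth %||% rep(1, K)
  topographies <- topographies %||% default_topographies(K, n_channels)

  cfg <- structure(list(
    preset = preset, n_subjects = as.integer(n_subjects),
    duration_s = duration_s, fs_raw = fs_raw, fs_env = fs_env,
    n_channels = as.integer(n_channels), K = as.integer(K),
    occupancy = occupancy, self_trans = self_trans,
    topographies = topographies, depth = depth, state_depth = state_depth,
    leakage = leakage, noise_sd = noise_sd,
    ultraslow_hz = ultraslow_hz, ultraslow_gain = ultraslow_gain,
    ultraslow_state = as.integer(ultraslow_state),
    ultraslow_amp = ultraslow_amp,
    group = group, seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1) stopf("n_subjects must be >= 1")
    if (duration_s <= 0) stopf("duration_s must be positive")
    if (n_channels < 1) stopf("n_channels must be >= 1")
    if (K < 1) stopf("K must be >= 1")
    if (fs_raw %% fs_env != 0) stopf("fs_env must divide fs_raw")
    if ((duration_s * fs_raw) %% 1 != 0)
      stopf("duration_s * fs_raw must be integral")
    if (length(occupancy) != K || abs(sum(occupancy) - 1) > 1e-8)
      stopf("occupancy must be length K and sum to 1")
    if (any(occupancy <= 0)) stopf("occupancy targets must be positive")
    if (length(self_trans) != K || any(self_trans < 0) ||
        any(self_trans >= 1))
      stopf("self_trans must be length K with values in [0, 1)")
    if (!all(dim(topographies) == c(K, n_channels)))
      stopf("topographies must be K x n_channels")
    if (any(topographies < 0)) stopf("topographies must be nonnegative")
    if (!is.null(leakage) && !all(dim(leakage) == c(n_channels, n_channels)))
      stopf("leakage must be n_channels x n_channels")
    if (ultraslow_gain != 0 && ultraslow_hz >= 0.1)
      stopf("ultraslow_hz must be below 0.1 Hz")
    if (abs(ultraslow_gain) > 1)
      stopf("ultraslow_gain must be in [-1, 1] to keep probabilities valid")
  })
  invisible(cfg)
}

#' Default block topographies
#'
#' Assigns each state a contiguous block of channels it modulates, spreading
#' blocks across the channel axis. Neighbouring states share no channels
#' when `width <= stride`.
#'
#' @param K Number of states.
#' @param M Number of channels.
#' @param width Channels modulated per state.
#' @return `K x M` 0/1 matrix.
#' @export
default_topographies <- function(K, M, width = 3) {
  topo <- matrix(0, K, M)
  stride <- if (K > 1) max(1L, (M - width) %/% (K - 1)) else 1L
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * stride + seq_len(width) - 1L) %% M + 1L
    topo[k, idx] <- 1
  }
  topo
}

#' Transition matrix with prescribed occupancy and dwell times
#'
#' Constructs a row-stochastic matrix whose diagonal equals `self_trans`
#' (fixing each state's geometric mean dwell) and whose stationary
#' distribution equals `occupancy`. Off-diagonal mass is distributed
#' proportionally to jump weights calibrated by a fixed-point iteration on
#' the stationary distribution.
#'
#' @param occupancy Target stationary distribution (sums to 1, positive).
#' @param self_trans Per-state self-transition probabilities in `[0, 1)`.
#' @param tol Convergence tolerance on the stationary distribution.
#' @return `K x K` transition matrix.
#' @export
transition_from_occupancy <- function(occupancy, self_trans, tol = 1e-12) {
  K <- length(occupancy)
  if (K == 1) return(matrix(1, 1, 1))
  stopifnot(length(self_trans) == K)
  w <- occupancy * (1 - self_trans)  # visit rates
  build <- function(w) {
    A <- matrix(0, K, K)
    for (k in seq_len(K)) {
      off <- w; off[k] <- 0
      A[k, ] <- (1 - self_trans[k]) * off / sum(off)
      A[k, k] <- self_trans[k]
    }
    A
  }
  for (iter in 1:500) {
    A <- build(w)
    st <- stationary_distribution(A)
    if (max(abs(st - occupancy)) < tol) break
    w <- w * occupancy / st
    w <- w / sum(w)
  }
  A
}

#' Stationary distribution of a finite Markov chain
#'
#' @param A Row-stochastic transition matrix.
#' @return Probability vector `p` with `p %*% A = p`.
#' @export
stationary_distribution <- function(A) {
  check_stochastic(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  p <- Re(e$vectors[, i])
  p / sum(p)
}

#' Simulate a latent state path
#'
#' Draws a length-`T` realization of a first-order Markov chain.
#'
#' @param A `K x K` row-stochastic transition matrix.
#' @param pi Initial distribution (length `K`, sums to 1).
#' @param T_len Number of samples.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param entry_scale Optional length-`T` multiplier on the probability of
#'   entering `coupled_state` at each step (rows renormalized); used for
#'   ultra-slow occurrence-rate coupling.
#' @param coupled_state State whose entry probability `entry_scale` scales.
#' @return Integer vector of states in `1..K`.
#' @export
simulate_state_sequence <- function(A, pi, T_len, seed = NULL,
                                    entry_scale = NULL,
                                    coupled_state = 1L) {
  check_stochastic(A)
  K <- nrow(A)
  if (length(pi) != K || abs(sum(pi) - 1) > 1e-8)
    stopf("pi must be a length-K probability vector")
  T_len <- as.integer(T_len)
  if (T_len < 1) stopf("T_len must be >= 1")
  if (!is.null(entry_scale)) {
    if (length(entry_scale) != T_len)
      stopf("entry_scale must have length T_len")
    if (any(entry_scale < 0))
      stopf("entry_scale implies negative entry probabilities")
  }
  with_seed(seed, {
    u <- runif(T_len)
    s <- integer(T_len)
    s[1] <- findInterval(u[1], cumsum(pi), left.open = TRUE) + 1L
    if (T_len == 1L) {
    } else if (is.null(entry_scale)) {
      cumA <- t(apply(A, 1, cumsum))
      for (t in 2:T_len)
        s[t] <- findInterval(u[t], cumA[s[t - 1], ], left.open = TRUE) + 1L
    } else {
      cumA <- t(apply(A, 1, cumsum))
      for (t in 2:T_len) {
        prev <- s[t - 1]
        if (prev == coupled_state) {
          # staying is not an entry: the schedule leaves self-rows alone
          s[t] <- findInterval(u[t], cumA[prev, ], left.open = TRUE) + 1L
        } else {
          p <- A[prev, ]
          p[coupled_state] <- p[coupled_state] * entry_scale[t]
          if (p[coupled_state] > 1)
            stopf("entry_scale drives an entry probability above 1")
          p <- p / sum(p)
          s[t] <- findInterval(u[t], cumsum(p), left.open = TRUE) + 1L
        }
      }
    }
    s
  })
}

#' Ultra-slow occurrence-rate modulator
#'
#' Produces the sinusoidal modulator (at the envelope rate) and the entry
#' probability schedule that couples the occurrence rate of one state to an
#' ultra-slow (< 0.1 Hz) potential.
#'
#' @param cfg A [synth_config()].
#' @param T_env Path length at the envelope rate (defaults to
#'   `duration_s * fs_env`).
#' @param phase Phase offset in radians.
#' @return List with `modulator` (length `T_env`, in `[-1, 1]`) and
#'   `entry_scale` (`1 + gain * modulator`).
#' @export
simulate_ultraslow_modulation <- function(cfg, T_env = NULL, phase = 0) {
  if (cfg$ultraslow_hz >= 0.1)
    stopf("ultraslow_hz must be below 0.1 Hz")
  T_env <- T_env %||% as.integer(cfg$duration_s * cfg$fs_env)
  tt <- (seq_len(T_env) - 1) / cfg$fs_env
  m <- sin(2 * pi * cfg$ultraslow_hz * tt + phase)
  scale <- 1 + cfg$ultraslow_gain * m
  if (any(scale < 0))
    stopf("ultraslow_gain produces negative entry probabilities")
  list(modulator = m, entry_scale = scale)
}

# Band-limited Gaussian carrier matrix (T x M), zero-phase filtered white
# noise in [low, high] Hz, scaled to unit variance then noise_sd.
carrier_matrix <- function(T_len, M, fs, low = 4, high = 30, noise_sd = 1) {
  bf <- signal::butter(5, c(low, high) / (fs / 2), type = "pass")
  x <- matrix(rnorm(T_len * M), T_len, M)
  for (m in seq_len(M)) {
    y <- signal::filtfilt(bf, x[, m])
    x[, m] <- y / sd(y) * noise_sd
  }
  x
}

#' Simulate a ground-truthed cohort
#'
#' Generates one cohort of per-subject raw recordings. For each subject a
#' latent state path is drawn at the envelope rate, sample-held up to the
#' raw rate, and used to scale the instantaneous amplitude of band-limited
#' (4-30 Hz) Gaussian carriers: channel m is multiplied by
#' `1 + depth * state_depth[k] * topographies[k, m]` while state k is
#' active. Optional zero-lag leakage mixing and an additive ultra-slow
#' potential are applied afterwards.
#'
#' @param cfg A [synth_config()].
#' @return List with `raw` (list of `T_raw x M` matrices, one per subject,
#'   with `fs` attribute), and `truth` (ground-truth paths at the envelope
#'   rate, planted transition matrix, topographies, modulators, group label,
#'   and the config).
#' @export
simulate_cohort <- function(cfg) {
  validate_synth_config(cfg)
  T_env <- as.integer(cfg$duration_s * cfg$fs_env)
  T_raw <- as.integer(cfg$duration_s * cfg$fs_raw)
  hold <- cfg$fs_raw %/% cfg$fs_env
  A <- transition_from_occupancy(cfg$occupancy, cfg$self_trans)
  pi0 <- stationary_distribution(A)
  seeds <- sub_seeds(cfg$seed, 3L * cfg$n_subjects)
  gain <- matrix(1 + cfg$depth * cfg$state_depth * cfg$topographies,
                 cfg$K, cfg$n_channels)
  raw <- vector("list", cfg$n_subjects)
  paths <- vector("list", cfg$n_subjects)
  modulators <- if (cfg$ultraslow_gain != 0) vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    mod <- NULL
    if (cfg$ultraslow_gain != 0) {
      phase <- with_seed(seeds[[3 * s - 2]], runif(1, 0, 2 * pi))
      mod <- simulate_ultraslow_modulation(cfg, T_env, phase)
      modulators[[s]] <- mod$modulator
    }
    path <- simulate_state_sequence(
      A, pi0, T_env, seed = seeds[[3 * s - 1]],
      entry_scale = mod$entry_scale, coupled_state = cfg$ultraslow_state)
    x <- with_seed(seeds[[3 * s]],
                   carrier_matrix(T_raw, cfg$n_channels, cfg$fs_raw,
                                  noise_sd = cfg$noise_sd))
    path_raw <- rep(path, each = hold)
    x <- x * gain[path_raw, , drop = FALSE]
    if (!is.null(cfg$leakage)) x <- x %*% t(cfg$leakage)
    if (!is.null(mod)) {
      slow <- rep(mod$modulator, each = hold) * cfg$ultraslow_amp
      coupled_ch <- which(cfg$topographies[cfg$ultraslow_state, ] > 0)
      x[, coupled_ch] <- x[, coupled_ch] + slow
    }
    attr(x, "fs") <- cfg$fs_raw
    raw[[s]] <- x
    paths[[s]] <- path
  }
  list(raw = raw,
       truth = list(paths = paths, A = A, occupancy = cfg$occupancy,
                    topographies = cfg$topographies,
                    modulators = modulators,
                    group = cfg$group, fs_env = cfg$fs_env, config = cfg))
}

#' Spectrally matched stationary surrogates
#'
#' Generates stationary Gaussian datasets matched to a reference
#' multichannel series in per-channel power spectra and zero-lag
#' cross-correlation. White noise is colored per channel by the reference's
#' (smoothed) amplitude spectrum, and the reference correlation structure is
#' then imposed through the symmetric square root of its correlation
#' matrix; channel means and standard deviations are restored last.
#'
#' @param reference `T x M` matrix (raw signal or envelopes), `M >= 2`,
#'   `T > M`.
#' @param n_datasets Number of surrogate datasets.
#' @param seed Integer seed.
#' @param spec_smooth Half-width (bins) of the moving-average smoother
#'   applied to the reference amplitude spectrum.
#' @return List of `n_datasets` matrices of the reference's dimensions.
#' @export
simulate_surrogate <- function(reference, n_datasets = 100, seed = NULL,
                               spec_smooth = 5) {
  if (!is.matrix(reference) || ncol(reference) < 2)
    stopf("reference must be a matrix with >= 2 channels")
  T_len <- nrow(reference); M <- ncol(reference)
  if (T_len <= M) stopf("reference must have T > M")
  mu <- colMeans(reference)
  sds <- apply(reference, 2, sd)
  C <- cor(reference)
  ev <- eigen(C, symmetric = TRUE)
  rk <- sum(ev$values > 1e-10 * max(ev$values))
  if (rk < M)
    stopf("reference covariance is singular (rank %d of %d)", rk, M)
  Chalf <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  # per-channel amplitude spectra (Hermitian-symmetric by construction)
  amp <- Mod(stats::mvfft(sweep(reference, 2, mu)))
  if (spec_smooth > 0) {
    w <- 2 * spec_smooth + 1
    kern <- rep(1 / w, w)
    amp <- apply(amp, 2, function(a) {
      n <- length(a)
      ap <- stats::filter(c(a[(n - w + 1):n], a, a[1:w]), kern,
                          sides = 2, circular = FALSE)
      as.numeric(ap[(w + 1):(w + n)])
    })
    # restore exact symmetry amp[i] == amp[n - i + 2]
    n <- nrow(amp)
    if (n > 2) {
      i <- 2:ceiling((n + 1) / 2)
      j <- n - i + 2
      avg <- (amp[i, , drop = FALSE] + amp[j, , drop = FALSE]) / 2
      amp[i, ] <- avg; amp[j, ] <- avg
    }
  }
  seeds <- sub_seeds(seed, n_datasets)
  lapply(seq_len(n_datasets), function(d) {
    z <- with_seed(seeds[[d]], matrix(rnorm(T_len * M), T_len, M))
    zf <- stats::mvfft(z) * amp
    zc <- Re(stats::mvfft(zf, inverse = TRUE)) / T_len
    zc <- scale(zc)
    y <- zc %*% Chalf
    y <- sweep(sweep(y, 2, apply(y, 2, sd), "/"), 2, sds, "*")
    y <- sweep(y, 2, mu, "+")
    attr(y, "fs") <- attr(reference, "fs")
    y
  })
}
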