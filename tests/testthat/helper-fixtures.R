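# Small in-code fixtures shared across test files.

# tiny two-state chain with strong self-persistence
toy_chain <- function(p = 0.8) {
  matrix(c(p, 1 - p, 1 - p, p), 2, byrow = TRUE)
}

# short synthetic cohort small enough for unit tests (not the study-scale
# preset): K states on few channels, a couple of minutes per subject
tiny_cohort <- function(n_subjects = 2, duration_s = 90, K = 3,
                        n_channels = 9, seed = 42, ...) {
  synth_config(n_subjects = n_subjects, duration_s = duration_s, K = K,
               n_channels = n_channels,
               occupancy = rep(1 / K, K), self_trans = rep(0.8, K),
               seed = seed, ...)
}

# exhaustive most-probable-path search over all K^T sequences (oracle for
# Viterbi); works directly from Gaussian parameters
brute_force_viterbi <- function(X, mu, Sigma, A, pi0) {
  T_len <- nrow(X); K <- ncol(mu)
  logd <- sapply(seq_len(K), function(k) {
    S <- Sigma[, , k]
    L <- chol(S)
    xc <- sweep(X, 2, mu[, k])
    z <- xc %*% solve(L)
    -0.5 * ncol(X) * log(2 * pi) - sum(log(diag(L))) - 0.5 * rowSums(z^2)
  })
  logd <- matrix(logd, nrow = T_len)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  score <- apply(grid, 1, function(s) {
    lp <- log(pi0[s[1]]) + logd[1, s[1]]
    if (T_len > 1)
      for (t in 2:T_len)
        lp <- lp + log(A[s[t - 1], s[t]]) + logd[t, s[t]]
    lp
  })
  grid[which.max(score), ]
}

# residualization-based partial correlation oracle: cor of the residuals of
# y and x_k after regressing both on the remaining design columns
pcor_residualization <- function(D, y) {
  vapply(seq_len(ncol(D)), function(k) {
    others <- D[, -k, drop = FALSE]
    ry <- stats::resid(stats::lm(y ~ others))
    rx <- stats::resid(stats::lm(D[, k] ~ others))
    stats::cor(ry, rx)
  }, numeric(1))
}
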