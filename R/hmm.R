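#' Fit a Gaussian-observation hidden Markov model
#'
#' Fits a K-state HMM in which each state emits a multivariate normal
#' distribution over channels (mean vector and full covariance), by
#' Baum-Welch expectation-maximization on the concatenated envelope matrix.
#' `n_restarts` independent initializations are run — each assigns time
#' points to states at random and takes means/covariances from that
#' assignment — and the restart with the highest log-likelihood is
#' returned.
#'
#' @param data An `env_concat` from [prepare_envelopes()] /
#'   [normalize_concatenate()], or a bare `T x M` matrix.
#' @param K Number of states (default 10).
#' @param n_restarts Independent EM initializations (default 10).
#' @param max_iter EM iteration cap per restart.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param seed Integer seed controlling all initializations.
#' @param ridge Covariance ridge, as a fraction of the mean diagonal.
#' @param eig_floor Eigenvalue floor for covariance regularization.
#' @return An object of class `envstates_hmm`: `K`, `M`, `mu` (`M x K`),
#'   `Sigma` (`M x M x K`), `A`, `pi`, `loglik`, `restart_logliks`,
#'   `trace` (per-iteration log-likelihood of the winning restart),
#'   `n_iter`, `converged`, `regularized`, `seed`, and the subject
#'   `lengths`/`fs` when `data` is an `env_concat`.
#' @export
fit_hmm <- function(data, K = 10, n_restarts = 10, max_iter = 500,
                    tol = 1e-6, seed = 1L, ridge = 1e-6,
                    eig_floor = 1e-10) {
  K <- as.integer(K)
  if (K < 1) stopf("K must be >= 1")
  X <- if (inherits(data, "env_concat")) data$values else as.matrix(data)
  if (!all(is.finite(X))) stopf("data contains non-finite values")
  T_len <- nrow(X); M <- ncol(X)
  seeds <- sub_seeds(seed, n_restarts)
  best <- NULL
  restart_ll <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seeds[[r]], sample.int(K, T_len, replace = TRUE))
    # every state must receive at least one time point
    missing <- setdiff(seq_len(K), unique(init))
    if (length(missing))
      init[sample.int(T_len, length(missing))] <- missing
    fit <- .ghmm_em(X, init, K, max_iter, tol, ridge, eig_floor)
    restart_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(
    K = K, M = M, mu = best$mu, Sigma = array(best$Sigma, c(M, M, K)),
    A = best$A, pi = as.numeric(best$pi), loglik = best$loglik,
    restart_logliks = restart_ll, trace = as.numeric(best$trace),
    n_iter = best$n_iter, converged = best$n_iter < max_iter,
    regularized = isTRUE(best$regularized), n_restarts = n_restarts,
    seed = seed,
    lengths = if (inherits(data, "env_concat")) data$lengths,
    fs = if (inherits(data, "env_concat")) data$fs),
    class = "envstates_hmm")
}

#' @export
print.envstates_hmm <- function(x, ...) {
  cat(sprintf("Gaussian-observation HMM: K = %d states, M = %d channels\n",
              x$K, x$M))
  cat(sprintf("log-likelihood %.2f (best of %d restarts, %d EM iterations%s)\n",
              x$loglik, x$n_restarts, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Posterior state probabilities (forward-backward)
#'
#' @param params An `envstates_hmm`.
#' @param data Matrix or `env_concat` with matching channel count.
#' @return List with `gamma` (`T x K` posteriors, rows sum to 1),
#'   `xi_sum` (expected transition counts), `loglik`.
#' @export
posterior_probabilities <- function(params, data) {
  X <- if (inherits(data, "env_concat")) data$values else as.matrix(data)
  if (ncol(X) != params$M)
    stopf("data has %d channels but the model expects %d",
          ncol(X), params$M)
  .ghmm_forward_backward(X, params$mu, params$Sigma, params$A,
                         matrix(params$pi, 1))
}

#' Viterbi decoding of the most probable state path
#'
#' Computes the globally most probable state sequence in the log domain;
#' ties break toward the lowest state index.
#'
#' @param params An `envstates_hmm`.
#' @param data Matrix or `env_concat`; when an `env_concat` is supplied the
#'   decoding restarts at every subject boundary using the model's
#'   stationary distribution.
#' @return Integer vector (length `T`) of states in `1..K`, with `fs`
#'   attribute when available.
#' @export
viterbi_decode <- function(params, data) {
  if (inherits(data, "env_concat")) {
    paths <- lapply(split_subjects(data), function(X)
      viterbi_decode(params, X))
    out <- unlist(paths)
    attr(out, "fs") <- data$fs
    return(out)
  }
  X <- as.matrix(data)
  if (ncol(X) != params$M)
    stopf("data has %d channels but the model expects %d",
          ncol(X), params$M)
  start <- if (params$K == 1) 1 else stationary_distribution(params$A)
  path <- .ghmm_viterbi(X, params$mu, params$Sigma, params$A,
                        matrix(start, 1))
  attr(path, "fs") <- attr(data, "fs")
  path
}

#' One-hot state indicator matrix
#'
#' @param path Integer state path with values in `1..K`.
#' @param K Number of states.
#' @return `T x K` binary matrix with exactly one 1 per row.
#' @export
state_indicators <- function(path, K) {
  path <- as.integer(path)
  if (any(path < 1L | path > K))
    stopf("path contains states outside 1..%d", K)
  ind <- matrix(0L, length(path), K)
  ind[cbind(seq_along(path), path)] <- 1L
  ind
}

# spatial signature per state: K x M matrix (state means over channels)
state_maps_of <- function(x) {
  if (inherits(x, "envstates_hmm")) return(t(x$mu))
  if (is.matrix(x)) return(x)
  stopf("expected an envstates_hmm fit or a K x M map matrix")
}

#' Match states between two fits (or a fit and reference maps)
#'
#' Finds the one-to-one assignment of states that maximizes the total
#' Pearson correlation between spatial signatures (state mean vectors, or
#' supplied `K x M` topography maps), by exact subset-DP optimal
#' assignment.
#'
#' @param a,b `envstates_hmm` fits or `K x M` map matrices with equal `K`.
#' @return Integer permutation `p`: state `i` of `a` corresponds to state
#'   `p[i]` of `b`. Attribute `correlations` holds the matched
#'   correlations.
#' @export
match_states <- function(a, b) {
  Ma <- state_maps_of(a); Mb <- state_maps_of(b)
  if (nrow(Ma) != nrow(Mb)) stopf("state counts differ (%d vs %d)",
                                  nrow(Ma), nrow(Mb))
  K <- nrow(Ma)
  C <- suppressWarnings(cor(t(Ma), t(Mb)))  # constant rows yield NA
  C[!is.finite(C)] <- -1
  p <- optimal_assignment(C)
  attr(p, "correlations") <- C[cbind(seq_len(K), p)]
  p
}

# Exact maximum-total-score assignment via DP over column subsets.
optimal_assignment <- function(score) {
  K <- nrow(score)
  if (K > 20) stopf("assignment DP supports K <= 20")
  nmask <- bitwShiftL(1L, K)
  best <- rep(-Inf, nmask)
  choice <- matrix(NA_integer_, K, nmask)
  best[1] <- 0
  for (mask in 0:(nmask - 2)) {
    if (!is.finite(best[mask + 1])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1))) != 0) + 1L  # next row
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0) next
      nm <- bitwOr(mask, bit)
      v <- best[mask + 1] + score[i, j]
      if (v > best[nm + 1]) {
        best[nm + 1] <- v
        choice[i, nm + 1] <- j
      }
    }
  }
  # backtrack
  p <- integer(K)
  mask <- nmask - 1L
  for (i in K:1) {
    j <- choice[i, mask + 1]
    p[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  p
}

#' @rdname tidy.envstates_hmm
#' @export
glance.envstates_hmm <- function(x, ...) {
  tibble::tibble(K = x$K, M = x$M, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged,
                 n_restarts = x$n_restarts, regularized = x$regularized)
}

#' Tidy / summarize a fitted HMM
#'
#' `tidy()` returns one row per state x channel with the state mean and
#' standard deviation; `glance()` returns a one-row model summary.
#'
#' @param x An `envstates_hmm`.
#' @param ... Unused.
#' @export
tidy.envstates_hmm <- function(x, ...) {
  sds <- vapply(seq_len(x$K), function(k) sqrt(diag(x$Sigma[, , k])),
                numeric(x$M))
  tibble::tibble(
    state = rep(seq_len(x$K), each = x$M),
    channel = rep(seq_len(x$M), x$K),
    mean = as.numeric(x$mu),
    sd = as.numeric(sds))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Heat-map of state mean topographies
#'
#' @param object An `envstates_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envstates_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$channel,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "state", y = "channel", fill = "mean\nenvelope",
                  title = "State mean topographies")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
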