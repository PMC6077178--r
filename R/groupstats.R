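# Welch t statistic for one permutation layout; x pooled values, g logical
# membership of group a.
welch_t <- function(x, in_a) {
  a <- x[in_a]; b <- x[!in_a]
  va <- var(a) / length(a); vb <- var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# all (or sampled) group-a index sets for a two-group permutation scheme
perm_assignments <- function(n, na, n_perm, seed) {
  n_total <- choose(n, na)
  if (n_total <= n_perm) {
    sets <- combn(n, na)
    list(sets = sets, exhaustive = TRUE)
  } else {
    sets <- with_seed(seed, replicate(n_perm, sample.int(n, na)))
    list(sets = sets, exhaustive = FALSE)
  }
}

#' Permutation t-test for a two-group difference
#'
#' Welch's t statistic, with a two-sided p-value from random permutation of
#' the group labels. When the number of distinct label arrangements is at
#' most `n_perm` the null is enumerated exhaustively (the observed split is
#' one of the arrangements); otherwise `n_perm` random relabelings are
#' drawn and the p-value uses the add-one estimator
#' `(1 + #{|t*| >= |t|}) / (1 + n_perm)`.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param n_perm Maximum number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `t`, `p`, `n_perm`, `exhaustive`.
#' @export
permutation_ttest <- function(values_a, values_b, n_perm = 10000,
                              seed = 1L) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 values")
  if (var(values_a) == 0 && var(values_b) == 0)
    stopf("zero variance in both groups")
  x <- c(values_a, values_b)
  t_obs <- welch_t(x, c(rep(TRUE, na), rep(FALSE, nb)))
  pa <- perm_assignments(na + nb, na, n_perm, seed)
  t_null <- apply(pa$sets, 2, function(idx) {
    in_a <- logical(na + nb); in_a[idx] <- TRUE
    welch_t(x, in_a)
  })
  n_used <- ncol(pa$sets)
  hits <- sum(abs(t_null) >= abs(t_obs) - 1e-12)
  p <- if (pa$exhaustive) hits / n_used else (1 + hits) / (1 + n_used)
  tibble::tibble(t = t_obs, p = p, n_perm = n_used,
                 exhaustive = pa$exhaustive)
}

#' Bartlett test of equal inter-subject variance
#'
#' Classical Bartlett chi-squared test for a difference in variance
#' between two groups.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
bartlett_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs >= 2 values")
  if (var(values_a) == 0 || var(values_b) == 0)
    stopf("zero variance group")
  bt <- bartlett.test(list(values_a, values_b))
  tibble::tibble(statistic = unname(bt$statistic),
                 df = unname(bt$parameter), p = bt$p.value)
}

# connected components of the subgraph induced by `active` nodes (BFS on a
# symmetric adjacency matrix); returns integer labels, 0 for inactive.
graph_components <- function(adj, active) {
  n <- length(active)
  comp <- integer(n)
  cur <- 0L
  for (v in which(active)) {
    if (comp[v]) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] != 0 & active & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Threshold-free cluster enhancement
#'
#' Enhances a channel-wise statistic map by integrating, over thresholds
#' `h`, `extent^E * h^H * dh` for the suprathreshold connected component
#' containing each channel. Negative values are enhanced separately on the
#' sign-flipped map, so the output is signed.
#'
#' @param stat Numeric statistic per channel.
#' @param adjacency Symmetric 0/1 channel adjacency matrix.
#' @param E,H TFCE extent and height exponents (defaults 0.5 and 2).
#' @param dh Threshold step; default `max(abs(stat)) / 100`.
#' @return Enhanced map, same length and signs as `stat`.
#' @export
tfce <- function(stat, adjacency, E = 0.5, H = 2, dh = NULL) {
  if (!is_square(adjacency) || nrow(adjacency) != length(stat))
    stopf("adjacency must be a square matrix matching stat")
  if (any(adjacency != t(adjacency))) stopf("adjacency must be symmetric")
  if (!is.null(dh) && dh <= 0) stopf("dh must be positive")
  enhance_pos <- function(s, dh) {
    out <- numeric(length(s))
    mx <- max(s)
    if (mx <= 0) return(out)
    dh <- dh %||% (mx / 100)
    if (mx < dh) return(out)  # below one threshold step: integral ~ 0
    for (h in seq(dh, mx, by = dh)) {
      comp <- graph_components(adjacency, s >= h)
      if (!any(comp)) next
      ext <- tabulate(comp)
      on <- comp > 0
      out[on] <- out[on] + ext[comp[on]]^E * h^H * dh
    }
    out
  }
  dh_use <- dh %||% if (max(abs(stat)) > 0) max(abs(stat)) / 100 else NULL
  enhance_pos(pmax(stat, 0), dh_use) - enhance_pos(pmax(-stat, 0), dh_use)
}

#' Group-difference map with TFCE family-wise error correction
#'
#' Channel-wise Welch t-map between two groups of subject maps, enhanced
#' by [tfce()], with family-wise-error-corrected p-values from the
#' permutation distribution of the maximum absolute enhanced statistic
#' under group-label exchange.
#'
#' @param maps_a,maps_b `M x n_subject` matrices (one column per subject)
#'   or lists of length-`M` vectors.
#' @param adjacency Symmetric channel adjacency matrix.
#' @param n_perm Maximum number of permutations.
#' @param seed Integer seed.
#' @param E,H,dh TFCE parameters (see [tfce()]).
#' @return Tibble with one row per channel: `channel`, `t`, `tfce`,
#'   `p_uncorrected` (permutation p of `|t|`), `p_corrected`
#'   (max-statistic TFCE-FWE p). Attributes record `n_perm` and
#'   `exhaustive`.
#' @export
fwe_map_test <- function(maps_a, maps_b, adjacency, n_perm = 1000,
                         seed = 1L, E = 0.5, H = 2, dh = NULL) {
  as_mat <- function(m) if (is.list(m)) do.call(cbind, m) else as.matrix(m)
  Ya <- as_mat(maps_a); Yb <- as_mat(maps_b)
  if (nrow(Ya) != nrow(Yb)) stopf("map shapes differ between groups")
  Y <- cbind(Ya, Yb)
  na <- ncol(Ya); n <- ncol(Y)
  tmap_for <- function(in_a) apply(Y, 1, function(x) welch_t(x, in_a))
  obs_in_a <- c(rep(TRUE, na), rep(FALSE, n - na))
  t_obs <- tmap_for(obs_in_a)
  enh_obs <- tfce(t_obs, adjacency, E = E, H = H, dh = dh)
  # fixed dh across permutations keeps the max statistic comparable
  dh_use <- dh %||% (max(abs(t_obs)) / 100)
  pa <- perm_assignments(n, na, n_perm, seed)
  n_used <- ncol(pa$sets)
  max_null <- numeric(n_used)
  t_null_ge <- numeric(length(t_obs))
  for (i in seq_len(n_used)) {
    in_a <- logical(n); in_a[pa$sets[, i]] <- TRUE
    t_perm <- tmap_for(in_a)
    enh <- tfce(t_perm, adjacency, E = E, H = H, dh = dh_use)
    max_null[i] <- max(abs(enh))
    t_null_ge <- t_null_ge + (abs(t_perm) >= abs(t_obs) - 1e-12)
  }
  if (pa$exhaustive) {
    p_unc <- t_null_ge / n_used
    p_cor <- vapply(abs(enh_obs), function(e)
      sum(max_null >= e - 1e-12) / n_used, numeric(1))
  } else {
    p_unc <- (1 + t_null_ge) / (1 + n_used)
    p_cor <- vapply(abs(enh_obs), function(e)
      (1 + sum(max_null >= e - 1e-12)) / (1 + n_used), numeric(1))
  }
  out <- tibble::tibble(channel = seq_along(t_obs), t = t_obs,
                        tfce = enh_obs, p_uncorrected = p_unc,
                        p_corrected = pmax(p_cor, p_unc))
  attr(out, "n_perm") <- n_used
  attr(out, "exhaustive") <- pa$exhaustive
  out
}

#' Block-structured channel adjacency
#'
#' Chain adjacency within consecutive channel blocks (used to give the
#' synthetic topography blocks a neighborhood structure for TFCE).
#'
#' @param M Number of channels.
#' @param block Block size; channels within a block form a path graph.
#' @return `M x M` symmetric 0/1 matrix.
#' @export
block_adjacency <- function(M, block = 4) {
  adj <- matrix(0, M, M)
  for (i in seq_len(M - 1)) {
    if ((i - 1) %/% block == i %/% block) {
      adj[i, i + 1] <- 1; adj[i + 1, i] <- 1
    }
  }
  adj
}
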