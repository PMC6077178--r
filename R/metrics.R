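#' Fractional occupancy
#'
#' Fraction of the recording spent in each state.
#'
#' @param path Integer state path in `1..K`.
#' @param K Number of states.
#' @return Length-`K` vector summing to 1.
#' @export
fractional_occupancy <- function(path, K) {
  if (!length(path)) stopf("empty path")
  tabulate(as.integer(path), nbins = K) / length(path)
}

# contiguous visits per state (rle segments)
visit_runs <- function(path) rle(as.integer(path))

#' Fractional count
#'
#' Number of visits (contiguous segments) to each state as a fraction of
#' the total number of visits across all states; boundary segments count as
#' full visits.
#'
#' @inheritParams fractional_occupancy
#' @return Length-`K` vector summing to 1.
#' @export
fractional_count <- function(path, K) {
  if (!length(path)) stopf("empty path")
  r <- visit_runs(path)
  tabulate(r$values, nbins = K) / length(r$values)
}

#' Mean lifetime
#'
#' Average duration of a visit to each state, in milliseconds. States never
#' visited are reported as `NA` (undefined), not zero.
#'
#' @inheritParams fractional_occupancy
#' @param fs Sampling rate of the path in Hz.
#' @return Length-`K` vector in ms.
#' @export
mean_lifetime <- function(path, K, fs) {
  if (!length(path)) stopf("empty path")
  r <- visit_runs(path)
  out <- vapply(seq_len(K), function(k) {
    len <- r$lengths[r$values == k]
    if (!length(len)) NA_real_ else mean(len) * 1000 / fs
  }, numeric(1))
  out
}

#' Empirical transition matrix
#'
#' Row-normalized counts of one-step transitions along the path. With
#' `mode = "exclude_self"` the diagonal is zeroed before renormalization,
#' describing where the path goes when it leaves a state.
#'
#' @inheritParams fractional_occupancy
#' @param mode `"with_self"` (default) or `"exclude_self"`.
#' @return `K x K` matrix; rows of never-visited states are `NA`.
#' @export
transition_matrix <- function(path, K,
                              mode = c("with_self", "exclude_self")) {
  mode <- match.arg(mode)
  path <- as.integer(path)
  if (length(path) < 2) stopf("path must have length >= 2")
  counts <- matrix(0, K, K)
  tab <- table(factor(head(path, -1), levels = 1:K),
               factor(tail(path, -1), levels = 1:K))
  counts <- matrix(as.numeric(tab), K, K)
  if (mode == "exclude_self") diag(counts) <- 0
  rs <- rowSums(counts)
  out <- counts / ifelse(rs > 0, rs, NA_real_)
  out
}

#' Sliding-window state occurrence rate
#'
#' Proportion of time spent in each state inside a sliding window (default
#' 5 s, half a cycle of a 0.1 Hz oscillation), the long-timescale
#' occurrence-rate time-course used for ultra-slow coupling maps.
#'
#' @inheritParams mean_lifetime
#' @param window_s Window length in seconds.
#' @param step Step between window starts, in samples.
#' @return `(T - window + 1) x K` matrix (rows subsampled by `step`) with
#'   attributes `fs`, `window_samples`, `step`.
#' @export
occurrence_rate_timecourse <- function(path, K, fs, window_s = 5,
                                       step = 1) {
  w <- round(window_s * fs)
  T_len <- length(path)
  if (T_len < w) stopf("path (%d samples) shorter than window (%d)",
                       T_len, w)
  ind <- state_indicators(path, K)
  cs <- rbind(0, apply(ind, 2, cumsum))
  starts <- seq(1L, T_len - w + 1L, by = step)
  rates <- (cs[starts + w, , drop = FALSE] -
              cs[starts, , drop = FALSE]) / w
  attr(rates, "fs") <- fs
  attr(rates, "window_samples") <- w
  attr(rates, "step") <- step
  rates
}

#' Per-subject temporal metrics table
#'
#' Computes fractional occupancy, fractional count, and mean lifetime for
#' one subject's decoded path, in tidy long form.
#'
#' @inheritParams mean_lifetime
#' @param subject,group Identifier columns attached to the output.
#' @return Tibble with columns `subject`, `group`, `state`, `fo`, `fc`,
#'   `lt_ms`.
#' @export
temporal_metrics <- function(path, K, fs, subject = 1L,
                             group = NA_character_) {
  tibble::tibble(
    subject = subject, group = group, state = seq_len(K),
    fo = fractional_occupancy(path, K),
    fc = fractional_count(path, K),
    lt_ms = mean_lifetime(path, K, fs))
}

#' Temporal metrics for a cohort of decoded paths
#'
#' @param paths List of per-subject state paths.
#' @param K Number of states.
#' @param fs Path sampling rate in Hz.
#' @param groups Group label per subject (recycled if length 1).
#' @param subjects Subject identifiers (default `1..n`).
#' @return Tibble, one row per subject x state (see [temporal_metrics()]).
#' @export
cohort_metrics <- function(paths, K, fs, groups = NA_character_,
                           subjects = seq_along(paths)) {
  groups <- rep_len(groups, length(paths))
  purrr::list_rbind(purrr::pmap(
    list(paths, subjects, groups),
    function(p, s, g) temporal_metrics(p, K, fs, subject = s, group = g)))
}

#' Box-plot of temporal metrics by group
#'
#' @param metrics Tibble from [cohort_metrics()].
#' @param metric One of `"fo"`, `"fc"`, `"lt_ms"`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics, metric = c("fo", "fc", "lt_ms")) {
  metric <- match.arg(metric)
  lab <- c(fo = "fractional occupancy", fc = "fractional count",
           lt_ms = "mean lifetime (ms)")[[metric]]
  ggplot2::ggplot(metrics,
                  ggplot2::aes(factor(.data$state), .data[[metric]],
                               fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "state", y = lab, fill = "group")
}
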