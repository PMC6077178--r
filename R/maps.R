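#' GLM design matrix from state indicators
#'
#' Builds the time x states design used for partial-correlation mapping.
#' An optional set of state columns is collapsed into a single regressor by
#' logical OR before z-scoring (e.g. the four-into-one collapsed design
#' that probes regions engaged across several states); the combined column
#' takes the position of the first collapsed state.
#'
#' @param ind `T x K` indicator matrix from [state_indicators()].
#' @param collapse Optional integer vector of state columns to merge.
#' @return `T x K'` matrix, each column z-scored; attributes `labels` and
#'   `collapse`.
#' @export
build_design <- function(ind, collapse = NULL) {
  K <- ncol(ind)
  labels <- as.character(seq_len(K))
  if (!is.null(collapse)) {
    collapse <- sort(unique(as.integer(collapse)))
    if (any(collapse < 1 | collapse > K))
      stopf("collapse labels outside 1..%d", K)
    if (length(collapse) < 2) stopf("collapse needs >= 2 states")
    merged <- as.integer(rowSums(ind[, collapse, drop = FALSE]) > 0)
    keep <- setdiff(seq_len(K), collapse[-1])
    ind <- ind[, keep, drop = FALSE]
    ind[, which(keep == collapse[1])] <- merged
    labels <- labels[keep]
    labels[keep == collapse[1]] <- paste(collapse, collapse = "+")
  }
  D <- apply(ind, 2, zscore)
  attr(D, "labels") <- labels
  attr(D, "collapse") <- collapse
  D
}

# Moore-Penrose pseudoinverse of a symmetric matrix
pinv_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

# partial correlations of each column of Y with each column of D, each
# controlling for the remaining columns of D, via the (generalized)
# precision matrix of cor(cbind(D, y)). A complete one-hot state design is
# exactly collinear after centering (its columns sum to a constant), so the
# pseudoinverse is used: for full-rank designs it coincides with the exact
# precision, hence with residualization-based partial correlations.
pcor_matrix <- function(D, Y) {
  Kp <- ncol(D)
  out <- matrix(NA_real_, ncol(Y), Kp)
  RD <- cor(D)
  full_rank <- rcond(RD) > 1e-10
  for (m in seq_len(ncol(Y))) {
    r_dy <- cor(D, Y[, m])
    R <- rbind(cbind(RD, r_dy), c(r_dy, 1))
    P <- if (full_rank) solve(R) else pinv_sym(R)
    d <- sqrt(abs(diag(P)))
    out[m, ] <- -P[seq_len(Kp), Kp + 1] / (d[seq_len(Kp)] * d[Kp + 1])
  }
  out
}

#' Partial-correlation state map
#'
#' For one subject, regresses the z-scored envelope of every channel on
#' the full state design; the coefficient reported for each state is the
#' partial correlation between that state's time-course and the channel
#' envelope, controlling for all other states. An optional time mask
#' restricts the rows (both design and envelopes are re-standardized
#' within the mask), e.g. to intervals of high occurrence rate.
#'
#' @param design `T x K'` design from [build_design()] (any column scaling;
#'   re-z-scored internally).
#' @param envelopes `T x M` envelope matrix for the same subject/rows.
#' @param mask Optional logical length-`T` vector selecting rows.
#' @return `state_map`: `M x K'` matrix of partial correlations with
#'   `labels` attribute.
#' @export
partial_correlation_map <- function(design, envelopes, mask = NULL) {
  if (nrow(design) != nrow(envelopes))
    stopf("design (%d rows) and envelopes (%d rows) are misaligned",
          nrow(design), nrow(envelopes))
  labels <- attr(design, "labels") %||% as.character(seq_len(ncol(design)))
  if (!is.null(mask)) {
    if (length(mask) != nrow(design)) stopf("mask length mismatch")
    design <- design[mask, , drop = FALSE]
    envelopes <- envelopes[mask, , drop = FALSE]
  }
  if (any(apply(design, 2, sd) == 0))
    stopf("design is rank deficient after masking (constant column)")
  D <- apply(design, 2, zscore)
  Y <- apply(envelopes, 2, zscore)
  out <- pcor_matrix(D, Y)
  dimnames(out) <- list(colnames(envelopes), labels)
  structure(out, class = c("state_map", "matrix"), labels = labels)
}

#' Narrow-band state maps
#'
#' Recomputes partial-correlation maps against narrow-band envelopes while
#' keeping the state time-courses from the wide-band fit (states are not
#' refit per band).
#'
#' @param design `T x K'` state design from the wide-band decoding.
#' @param band_envelopes Named list of `T x M` envelope matrices, one per
#'   band, aligned with the design rows.
#' @param mask Optional logical row mask (see
#'   [partial_correlation_map()]).
#' @return Named list of `state_map`s.
#' @export
band_specific_maps <- function(design, band_envelopes, mask = NULL) {
  lapply(band_envelopes, function(e)
    partial_correlation_map(design, e, mask = mask))
}

#' Average maps across subjects
#'
#' Element-wise mean of per-subject maps; with `use_absolute = TRUE` the
#' absolute values are averaged (used for ultra-slow coupling maps, where
#' the coupling phase — hence the coefficient sign — is ambiguous across
#' subjects).
#'
#' @param maps List of equal-shape map matrices.
#' @param use_absolute Average `|coefficients|` instead of signed values.
#' @return Map matrix of the common shape.
#' @export
average_maps <- function(maps, use_absolute = FALSE) {
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stopf("maps have mismatched shapes")
  if (use_absolute) maps <- lapply(maps, abs)
  out <- Reduce(`+`, maps) / length(maps)
  class(out) <- c("state_map", "matrix")
  out
}

#' Ultra-slow occurrence-rate coupling map
#'
#' Partial correlations between each channel of the lowpass (< 0.1 Hz)
#' signal and every state's sliding-window occurrence-rate time-course,
#' controlling for the other states' rates.
#'
#' @param rates `T' x K` occurrence-rate matrix from
#'   [occurrence_rate_timecourse()].
#' @param slow `T' x M` matrix (or vector) of ultra-slow signal values
#'   aligned with the rate windows.
#' @return `state_map`: `M x K` partial correlations.
#' @export
ultraslow_rate_map <- function(rates, slow) {
  if (!is.matrix(slow)) slow <- matrix(slow, ncol = 1)
  if (nrow(rates) != nrow(slow))
    stopf("rates (%d) and slow signal (%d) rows are misaligned",
          nrow(rates), nrow(slow))
  partial_correlation_map(rates, slow)
}

#' High-occurrence-rate time mask
#'
#' Marks the time points whose sliding-window occurrence rate for a state
#' falls in the top quartile (by default) of that state's rate
#' distribution. Window rates are assigned to window-start samples; the
#' trailing `window - 1` samples are excluded.
#'
#' @param rates Occurrence-rate matrix from
#'   [occurrence_rate_timecourse()] (step 1).
#' @param state State column the mask is built for.
#' @param prob Quantile defining "high" (default 0.75).
#' @param T_len Full path length the mask should span.
#' @return Logical vector of length `T_len`.
#' @export
high_rate_mask <- function(rates, state, prob = 0.75,
                           T_len = nrow(rates) + attr(rates, "window_samples") - 1L) {
  r <- rates[, state]
  thr <- quantile(r, prob)
  mask <- logical(T_len)
  mask[seq_along(r)] <- r >= thr
  mask
}

#' Session-average amplitude per channel and band
#'
#' Time-mean envelope of every channel in each band — the whole-recording
#' amplitude maps compared between groups.
#'
#' @param band_envelopes Named list of `T x M` envelope matrices.
#' @param subject Identifier attached to the output.
#' @return Tibble with columns `subject`, `band`, `channel`, `amplitude`.
#' @export
session_average_amplitude <- function(band_envelopes, subject = 1L) {
  purrr::list_rbind(purrr::imap(band_envelopes, function(e, band)
    tibble::tibble(subject = subject, band = band,
                   channel = seq_len(ncol(e)),
                   amplitude = colMeans(e))))
}

#' Long-format view of a state map
#'
#' @param x A `state_map`.
#' @param ... Unused.
#' @return Tibble with `channel`, `state`, `coefficient`.
#' @export
tidy.state_map <- function(x, ...) {
  labels <- attr(x, "labels") %||% as.character(seq_len(ncol(x)))
  tibble::tibble(
    channel = rep(seq_len(nrow(x)), ncol(x)),
    state = rep(labels, each = nrow(x)),
    coefficient = as.numeric(x))
}

#' Heat-map of a state map
#'
#' @param object A `state_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_map <- function(object, ...) {
  df <- tidy.state_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$channel,
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "state", y = "channel",
                  fill = "partial\ncorrelation")
}
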