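#' Write / read a matrix with a JSON sidecar header
#'
#' Matrices are stored as tab-delimited text (`time x channels`, full
#' double precision) next to a `<path>.json` sidecar recording the
#' sampling rate, channel names, and any extra metadata.
#'
#' @param m Numeric matrix.
#' @param path Output file path (the sidecar is `paste0(path, ".json")`).
#' @param fs Sampling rate in Hz (defaults to `attr(m, "fs")`).
#' @param channels Channel names (defaults to `chan1..chanM`).
#' @param ... Extra scalar metadata stored in the sidecar (e.g. `group`,
#'   `seed`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, fs = attr(m, "fs"), channels = NULL,
                         ...) {
  if (is.null(fs)) stopf("fs is required to write a matrix")
  channels <- channels %||% colnames(m) %||%
    paste0("chan", seq_len(ncol(m)))
  utils::write.table(format(m, digits = 17, trim = TRUE), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  header <- c(list(fs = fs, n_channels = ncol(m), n_samples = nrow(m),
                   channels = channels), list(...))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @return For `read_matrix()`: the matrix, with `fs`, `channels`, and
#'   `meta` attributes restored.
#' @export
read_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing sidecar header %s", sidecar)
  header <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(header$fs)) stopf("header %s does not declare fs", sidecar)
  widths <- utils::count.fields(path, sep = "\t")
  bad <- which(widths != widths[1])
  if (length(bad))
    stopf("ragged row in %s at line %d (%d fields, expected %d)",
          path, bad[1], widths[bad[1]], widths[1])
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  attr(m, "fs") <- header$fs
  attr(m, "channels") <- header$channels
  attr(m, "meta") <- header[setdiff(names(header),
                                    c("fs", "n_channels", "n_samples",
                                      "channels"))]
  m
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the synthetic cohort preset,
#' band, HMM size and restarts, metric windows, TFCE parameters, and the
#' master seed from which all stage seeds derive.
#'
#' @param preset Cohort preset passed to [synth_config()]
#'   (`"ch_default"`, `"ad_default"`).
#' @param n_subjects,duration_s,K Cohort shape (see [synth_config()]).
#' @param n_restarts HMM restarts.
#' @param band Analysis band (a [band_spec()]).
#' @param orthogonalize Leakage-correct before envelopes.
#' @param window_s Occurrence-rate window (s).
#' @param tfce_E,tfce_H TFCE exponents.
#' @param n_perm Permutations for group tests.
#' @param seed Master seed.
#' @param ... Extra fields forwarded to [synth_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "ch_default", n_subjects = 10,
                       duration_s = 540, K = 10, n_restarts = 10,
                       band = band_spec("wide"), orthogonalize = TRUE,
                       window_s = 5, tfce_E = 0.5, tfce_H = 2,
                       n_perm = 1000, seed = 1L, ...) {
  structure(list(preset = preset, n_subjects = n_subjects,
                 duration_s = duration_s, K = K, n_restarts = n_restarts,
                 band = band, orthogonalize = orthogonalize,
                 window_s = window_s, tfce_E = tfce_E, tfce_H = tfce_H,
                 n_perm = n_perm, seed = as.integer(seed),
                 extra = list(...)),
            class = "run_config")
}

#' Run the full state-segmentation pipeline on one synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> fit -> decode -> metrics ->
#' maps for a single cohort: generates the preset cohort, prepares
#' leakage-corrected wide-band envelopes at 20 Hz, fits the K-state HMM
#' with restarts, Viterbi-decodes each subject, computes the temporal
#' metrics table and per-subject/group partial-correlation maps, and
#' matches fitted states to the planted topographies.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, metrics, maps, decoded
#'   paths, and a JSON manifest of all parameters and seeds are written
#'   there.
#' @return List: `fit` (the `envstates_hmm`), `paths` (per-subject decoded
#'   paths), `metrics` (tibble, one row per subject x state),
#'   `subject_maps`, `group_map`, `match` (fitted state per planted
#'   state), `metrics_matched` (metrics relabeled to planted states),
#'   `truth`, `config`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- sub_seeds(cfg$seed, 2L)
  scfg <- do.call(synth_config, c(list(
    preset = cfg$preset, n_subjects = cfg$n_subjects,
    duration_s = cfg$duration_s, K = cfg$K, seed = seeds[[1]]),
    cfg$extra))
  cohort <- simulate_cohort(scfg)
  env <- prepare_envelopes(cohort$raw, band = cfg$band,
                           orthogonalize = cfg$orthogonalize)
  fit <- fit_hmm(env, K = cfg$K, n_restarts = cfg$n_restarts,
                 seed = seeds[[2]])
  subj_env <- split_subjects(env)
  paths <- lapply(subj_env, function(e) viterbi_decode(fit, e))
  metrics <- cohort_metrics(paths, K = cfg$K, fs = env$fs,
                            groups = scfg$group)
  subject_maps <- purrr::map2(paths, subj_env, function(p, e)
    partial_correlation_map(build_design(state_indicators(p, cfg$K)), e))
  group_map <- average_maps(subject_maps)
  # planted state k of the generator corresponds to fitted state
  # state_match[k]
  state_match <- match_states(cohort$truth$topographies, fit)
  metrics_matched <- dplyr::mutate(
    metrics, planted_state = match(.data$state, state_match))
  out <- list(fit = fit, paths = paths, metrics = metrics,
              subject_maps = subject_maps, group_map = group_map,
              match = state_match, metrics_matched = metrics_matched,
              truth = cohort$truth, config = cfg)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# serialize a pipeline run: tables as TSV, paths as delimited integers,
# manifest as JSON
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(unclass(run$group_map),
                     file.path(out_dir, "group_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (s in seq_along(run$paths))
    utils::write.table(as.integer(run$paths[[s]]),
                       file.path(out_dir, sprintf("path_subj%02d.tsv", s)),
                       row.names = FALSE, col.names = FALSE)
  cfg <- run$config
  manifest <- list(
    preset = cfg$preset, n_subjects = cfg$n_subjects,
    duration_s = cfg$duration_s, K = cfg$K,
    n_restarts = cfg$n_restarts, band = unclass(cfg$band),
    orthogonalize = cfg$orthogonalize, window_s = cfg$window_s,
    tfce = list(E = cfg$tfce_E, H = cfg$tfce_H), n_perm = cfg$n_perm,
    seed = cfg$seed, loglik = run$fit$loglik,
    converged = run$fit$converged, match = as.integer(run$match))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
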