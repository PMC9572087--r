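# Pipeline orchestration: a single config object with defaults for
# every stage, and run_pipeline() chaining
# segment -> extract -> normalize/discretise -> JMIM -> evaluate,
# writing plain-text artifacts plus a JSON run manifest.

#' Pipeline configuration with defaults for every stage
#'
#' @param window_seconds window length in seconds (default 2.5).
#' @param overlap_fraction window overlap in `[0, 1)` (default 0:
#'   sequential windows).
#' @param filter_cutoff,filter_order high-pass filter parameters
#'   (defaults 0.5 Hz, order 4).
#' @param acf_lags_s autocorrelation lags in seconds.
#' @param bands spectral bands (`NULL`: defaults derived from fs).
#' @param n_peaks,n_harmonics spectral peak and THD harmonic counts.
#' @param wavelet,wpd_levels,wpd_nodes wavelet packet parameters.
#' @param m,tau,eps_fraction,lmin embedding/recurrence parameters.
#' @param pe_order,pe_delay permutation-entropy parameters.
#' @param ar_order autoregressive model order (default 5).
#' @param n_bins equal-width discretisation bins (default 10).
#' @param folds cross-validation folds (default 5).
#' @param subset_sizes feature-curve subset sizes.
#' @param classifiers classifiers to evaluate.
#' @param ablation run the with/without-uncommon-features comparison.
#' @param seed seed for fold assignment (and synthetic generation when
#'   the pipeline creates its own input).
#' @return Named list of class `har_config`.
#' @export
har_config <- function(window_seconds = 2.5, overlap_fraction = 0,
                       filter_cutoff = 0.5, filter_order = 4,
                       acf_lags_s = c(0.2, 0.4, 0.6), bands = NULL,
                       n_peaks = 6, n_harmonics = 5,
                       wavelet = "db4", wpd_levels = 5, wpd_nodes = 3,
                       m = 3, tau = 1, eps_fraction = 0.2, lmin = 2,
                       pe_order = 3, pe_delay = 1, ar_order = 5,
                       n_bins = 10, folds = 5,
                       subset_sizes = c(1, 10, 30, 60, 120, 193),
                       classifiers = c("svm", "knn"),
                       ablation = TRUE, seed = 42) {
  structure(list(
    window_seconds = window_seconds, overlap_fraction = overlap_fraction,
    filter_cutoff = filter_cutoff, filter_order = filter_order,
    acf_lags_s = acf_lags_s, bands = bands, n_peaks = n_peaks,
    n_harmonics = n_harmonics, wavelet = wavelet,
    wpd_levels = wpd_levels, wpd_nodes = wpd_nodes, m = m, tau = tau,
    eps_fraction = eps_fraction, lmin = lmin, pe_order = pe_order,
    pe_delay = pe_delay, ar_order = ar_order, n_bins = n_bins,
    folds = folds, subset_sizes = subset_sizes,
    classifiers = classifiers, ablation = ablation, seed = seed
  ), class = "har_config")
}

# Polynomial rolling hash of the serialized config, for provenance in
# the manifest (stable across sessions; not cryptographic).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full feature-significance pipeline
#'
#' Segments the recording, extracts the 193-feature matrix, normalizes
#' and discretises it, ranks all features with JMIM, evaluates the
#' incremental feature curve with cross-validated classifiers and
#' (optionally) the with/without-uncommon-features ablation, and writes
#' plain-text artifacts to `out_dir`:
#' `features.csv`, `ranking.csv`, `curve.csv`, `report.json` (top
#' features with group tags plus the ablation pair) and `manifest.json`
#' (config, hash, package version, per-stage row counts).
#'
#' @param recording a [har_recording].
#' @param config a [har_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   file output.
#' @param top_k number of top-ranked features listed in the report.
#' @return List with `windows`, `features`, `normalized`, `ranking`,
#'   `curve`, `ablation` (or `NULL`), `report`, `manifest`, invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(recording, config = har_config(), out_dir = NULL,
                         top_k = 30) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  windows <- stage("segment", segment_recording(
    recording, config$window_seconds, config$overlap_fraction,
    config$filter_cutoff, config$filter_order))
  if (!length(windows)) stop("recording shorter than one window")
  features <- stage("extract", extract_features(windows, config))
  normalized <- stage("normalize", suppressWarnings(
    normalize_features(features)))
  disc <- stage("discretise", discretise_ewd(normalized, config$n_bins))
  labels <- attr(features, "labels")
  ranking <- stage("select", jmim_select(disc, labels))
  curve <- stage("evaluate", cross_validate(
    normalized, ranking, config$subset_sizes, config$classifiers,
    config$folds, config$seed, labels = labels))
  ablation <- NULL
  if (isTRUE(config$ablation))
    ablation <- stage("ablate", ablate_uncommon(
      normalized, classifier = config$classifiers[1],
      folds = config$folds, seed = config$seed, n_bins = config$n_bins,
      labels = labels))
  groups <- attr(features, "groups")
  kk <- min(top_k, length(ranking$order))
  report <- list(
    top_features = data.frame(
      rank = seq_len(kk),
      feature_name = ranking$feature_names[ranking$order[seq_len(kk)]],
      group = unname(groups[ranking$feature_names[ranking$order[seq_len(kk)]]]),
      score = ranking$scores[seq_len(kk)], stringsAsFactors = FALSE),
    group_counts_top_k = as.list(table(
      groups[ranking$feature_names[ranking$order[seq_len(kk)]]])),
    ablation = if (!is.null(ablation)) list(
      with_accuracy_macro = ablation$with$accuracy_macro,
      without_accuracy_macro = ablation$without$accuracy_macro,
      gain_accuracy_macro = ablation$gain_accuracy_macro,
      gain_accuracy_overall = ablation$gain_accuracy_overall)
  )
  manifest <- list(
    package = "harfeatures",
    version = as.character(packageVersion("harfeatures")),
    config = unclass(config),
    config_hash = config_hash(config),
    n_samples = length(recording$x),
    fs = recording$fs,
    n_windows = length(windows),
    n_features = ncol(features),
    n_curve_rows = nrow(curve)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fdf <- data.frame(label = as.character(labels), features,
                      check.names = FALSE)
    write.csv(fdf, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(as.data.frame(ranking), file.path(out_dir, "ranking.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(curve), file.path(out_dir, "curve.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(windows = windows, features = features,
                 normalized = normalized, ranking = ranking, curve = curve,
                 ablation = ablation, report = report, manifest = manifest))
}
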