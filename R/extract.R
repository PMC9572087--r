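# Feature registry and the per-window extraction orchestrator. The
# descriptor has exactly 193 named features in five groups:
#   time                      mean/std/rms (12), autocorrelation (12),
#                             PCA loadings (3), dxyz + sma (2)     = 29
#   frequency                 spectral peaks (48), band powers (12),
#                             FFT magnitudes + entropy (16), THD (4) = 80
#   time-frequency            WPD statistics                        = 36
#   repeatability-regularity  RQA + LLE + PE                        = 24
#   autoregression            Burg AR(5) + residual variance        = 24

SIGNALS <- c("x", "y", "z", "mg")

#' The feature registry: names and group membership
#'
#' Enumerates the 193 features in extraction order together with their
#' group (one of `time`, `frequency`, `time-frequency`,
#' `repeatability-regularity`, `autoregression`).
#'
#' @return A data.frame with columns `index`, `name`, `group`.
#' @export
feature_registry <- function() {
  nm <- character(0); gp <- character(0)
  add <- function(names, group) {
    nm <<- c(nm, names); gp <<- c(gp, rep(group, length(names)))
  }
  add(paste0("mean_", SIGNALS), "time")
  add(paste0("std_", SIGNALS), "time")
  add(paste0("rms_", SIGNALS), "time")
  for (s in SIGNALS) add(paste0("acf", 1:3, "_", s), "time")
  for (s in SIGNALS)
    add(paste0(as.vector(rbind(paste0("peak", 1:6, "_height"),
                               paste0("peak", 1:6, "_freq"))), "_", s),
        "frequency")
  for (s in SIGNALS) add(paste0("bandpower", 1:3, "_", s), "frequency")
  for (s in SIGNALS)
    add(paste0(c("fftmag1", "fftmag2", "fftmag3", "fftentropy"), "_", s),
        "frequency")
  for (s in SIGNALS)
    add(paste0("wpd_n", rep(1:3, each = 3), "_",
               rep(c("sumabs", "energy", "entropy"), 3), "_", s),
        "time-frequency")
  add(c("pca_pc1_x", "pca_pc1_y", "pca_pc1_z"), "time")
  for (s in SIGNALS)
    add(paste0(c("rqa_rr", "rqa_det", "rqa_entr", "rqa_l", "lle", "pe"),
               "_", s), "repeatability-regularity")
  add(paste0("thd_", SIGNALS), "frequency")
  add(c("dxyz", "sma"), "time")
  for (s in SIGNALS)
    add(paste0(c(paste0("ar", 1:5), "arvar"), "_", s), "autoregression")
  data.frame(index = seq_along(nm), name = nm, group = gp,
             stringsAsFactors = FALSE)
}

#' Names of the "uncommon" regularity-sensitive features
#'
#' The repeatability-regularity group (RQA, permutation entropy,
#' Lyapunov exponent) plus the four THD features: the feature set whose
#' ablation quantifies the contribution of signal-regularity
#' information.
#'
#' @return Character vector of 28 feature names.
#' @export
uncommon_features <- function() {
  reg <- feature_registry()
  c(reg$name[reg$group == "repeatability-regularity"],
    paste0("thd_", SIGNALS))
}

#' Extract the 193-feature descriptor for every window
#'
#' Runs every feature block on each window and assembles the
#' windows-by-193 feature matrix. Mean and standard deviation use the
#' raw channels; all other features use the high-pass-filtered channels
#' and the magnitude channel. Degenerate inputs (constant channels, flat
#' spectra) produce defined sentinel values rather than NaN; any
#' warnings raised along the way are collected and reported once.
#'
#' @param windows a `har_windows` object from [segment_recording()].
#' @param config a [har_config()] list controlling block parameters
#'   (autocorrelation lags, bands, wavelet, embedding, ...).
#' @return A numeric matrix of class `har_features` with 193 named
#'   columns and attributes `labels` (factor, one per window) and
#'   `groups` (named character vector mapping feature to group).
#' @export
extract_features <- function(windows, config = har_config()) {
  stopifnot(inherits(windows, "har_windows"))
  if (!length(windows)) stop("no windows to extract features from")
  reg <- feature_registry()
  warn_count <- 0L
  first_warn <- NULL
  rows <- withCallingHandlers(
    lapply(windows, function(w) window_features(w, config)),
    warning = function(cond) {
      warn_count <<- warn_count + 1L
      if (is.null(first_warn)) first_warn <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    }
  )
  m <- do.call(rbind, rows)
  stopifnot(ncol(m) == nrow(reg))
  colnames(m) <- reg$name
  bad <- !is.finite(m)
  if (any(bad)) {
    warning(sum(bad), " non-finite feature value(s) replaced by 0")
    m[bad] <- 0
  }
  if (warn_count > 0L)
    message(warn_count, " degenerate-input sentinel(s) during extraction ",
            "(first: ", first_warn, ")")
  structure(m, class = c("har_features", class(m)),
            labels = attr(windows, "labels"),
            groups = stats::setNames(reg$group, reg$name))
}

window_features <- function(w, config) {
  fs <- w$fs
  sigs <- list(x = w$xf, y = w$yf, z = w$zf, mg = w$mg)
  bands <- config$bands %||% default_bands(fs)
  peaks <- unlist(lapply(sigs, function(v)
    spectral_peaks(v, fs, config$n_peaks)), use.names = FALSE)
  bp <- unlist(lapply(sigs, function(v) band_power(v, fs, bands)),
               use.names = FALSE)
  ff <- unlist(lapply(sigs, function(v) fft_summary(v, fs)),
               use.names = FALSE)
  wp <- unlist(lapply(sigs, function(v)
    wpd_features(wpd_decompose(v, config$wavelet, config$wpd_levels),
                 config$wpd_nodes)), use.names = FALSE)
  th <- vapply(sigs, function(v) thd(v, fs, config$n_harmonics), numeric(1))
  c(basic_stats(w),
    autocorrelation_features(w, config$acf_lags_s),
    peaks, bp, ff, wp,
    pca_pc1(w),
    dynamics_features(w, config$m, config$tau, config$eps_fraction,
                      config$lmin, config$pe_order, config$pe_delay),
    th,
    geometry_features(w),
    ar_coefficients(w, config$ar_order))
}

#' @export
print.har_features <- function(x, ...) {
  cat(sprintf("<har_features> %d windows x %d features\n", nrow(x), ncol(x)))
  tab <- table(attr(x, "groups"))
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}
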