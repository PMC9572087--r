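#' Zero-phase IIR high-pass filter
#'
#' Removes the gravitational (DC and very-low-frequency) component of an
#' acceleration channel with a Butterworth high-pass applied
#' forward-backward ([signal::filtfilt()]), so the waveform is not phase
#' shifted. The default 0.5 Hz cutoff removes gravity while leaving the
#' gait band (roughly 1-3 Hz) untouched.
#'
#' @param channel numeric sample vector.
#' @param fs sampling frequency in Hz.
#' @param cutoff high-pass cutoff in Hz; must lie in `(0, fs/2)`.
#' @param order filter order (default 4).
#' @return Filtered vector of the same length.
#' @export
#' @examples
#' x <- 1 + sin(2 * pi * 2 * (0:99) / 50)  # gravity + 2 Hz gait
#' xf <- highpass(x, fs = 50)
#' c(mean(x), mean(xf))
highpass <- function(channel, fs, cutoff = 0.5, order = 4) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency fs/2")
  n <- length(channel)
  if (n <= 3 * order)
    stop("channel too short for a filter of order ", order)
  # the mean is pure DC: removing it first keeps edge transients small
  v <- channel - mean(channel)
  if (all(v == 0)) return(rep(0, n))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  # odd-reflection padding at both ends suppresses start-up transients;
  # its length scales with the filter time constant fs / (2 pi cutoff)
  p <- min(n - 1, max(3 * order, ceiling(3 * fs / cutoff)))
  front <- 2 * v[1] - v[(p + 1):2]
  back <- 2 * v[n] - v[(n - 1):(n - p)]
  out <- as.numeric(signal::filtfilt(bf, c(front, v, back)))
  out[(p + 1):(p + n)]
}

#' Segment a recording into fixed-length windows
#'
#' Slices the recording into windows of `window_seconds` with step
#' `round(window_seconds * fs * (1 - overlap_fraction))`; a trailing
#' partial window is dropped. Each window stores the raw channels, their
#' high-pass-filtered versions, the magnitude channel
#' `mg = sqrt(xf^2 + yf^2 + zf^2)` and the modal activity label of the
#' covered samples (ties broken by first-encountered label). The filter
#' is applied per window.
#'
#' @param recording a [har_recording].
#' @param window_seconds window length in seconds (default 2.5).
#' @param overlap_fraction fraction of overlap between consecutive
#'   windows, in `[0, 1)` (default 0: sequential windows).
#' @param cutoff,order high-pass parameters passed to [highpass()].
#' @return An object of class `har_windows`: a list of windows (each a
#'   list with `x`, `y`, `z`, `xf`, `yf`, `zf`, `mg`, `label`, `fs`) with
#'   attributes `fs` and `labels`. A recording shorter than one window
#'   yields an empty list.
#' @export
segment_recording <- function(recording, window_seconds = 2.5,
                              overlap_fraction = 0, cutoff = 0.5, order = 4) {
  stopifnot(inherits(recording, "har_recording"))
  fs <- recording$fs
  wlen <- round(window_seconds * fs)
  if (wlen < 2) stop("window_seconds * fs must be at least 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  check_uniform(recording)
  step <- max(1L, round(wlen * (1 - overlap_fraction)))
  n <- length(recording$x)
  if (n < wlen) {
    return(structure(list(), class = "har_windows", fs = fs,
                     labels = factor(character(0),
                                     levels = levels(recording$label))))
  }
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  wins <- lapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    x <- recording$x[idx]; y <- recording$y[idx]; z <- recording$z[idx]
    xf <- highpass(x, fs, cutoff, order)
    yf <- highpass(y, fs, cutoff, order)
    zf <- highpass(z, fs, cutoff, order)
    list(x = x, y = y, z = z, xf = xf, yf = yf, zf = zf,
         mg = sqrt(xf^2 + yf^2 + zf^2),
         label = modal_label(recording$label[idx]), fs = fs)
  })
  structure(wins, class = "har_windows", fs = fs,
            labels = factor(vapply(wins, `[[`, character(1), "label"),
                            levels = levels(recording$label)))
}

modal_label <- function(lab) {
  u <- unique(as.character(lab))  # first-encountered order breaks ties
  counts <- vapply(u, function(v) sum(lab == v), integer(1))
  u[which.max(counts)]
}

#' @export
print.har_windows <- function(x, ...) {
  cat(sprintf("<har_windows> %d windows @ %g Hz\n", length(x), attr(x, "fs")))
  if (length(x)) {
    tab <- table(attr(x, "labels"))
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Column-standardize a feature matrix
#'
#' Centres each feature to mean zero and scales to unit sample standard
#' deviation, `f <- (f - mean(f)) / sd(f)`. Zero-variance columns are set
#' to all zeros and flagged with a warning (they carry no information).
#'
#' @param matrix a numeric feature matrix (windows x features), e.g. from
#'   [extract_features()].
#' @return Matrix of the same shape and attributes, standardized.
#' @export
normalize_features <- function(matrix) {
  m <- matrix
  if (nrow(m) < 2) stop("need at least 2 windows to normalize")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    warning(sum(zero), " zero-variance feature(s) set to 0: ",
            paste(head(colnames(m)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ...")
  sdv[zero] <- 1
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  out[, zero] <- 0
  attributes(out)[names(attributes(m))] <- attributes(m)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Equal-width discretisation of a feature matrix
#'
#' Splits each feature's observed range into `n_bins` equal-width
#' intervals and maps values to integer bins `0 .. n_bins - 1` (the
#' column minimum falls in bin 0, the maximum in bin `n_bins - 1`).
#' Constant columns map entirely to bin 0. Discretised features feed the
#' mutual-information selector; classifiers use the continuous values.
#'
#' @param matrix numeric feature matrix (windows x features).
#' @param n_bins number of bins per feature, `>= 2` (default 10).
#' @return An object of class `har_discretised`: list with `bins`
#'   (integer matrix, 0-based), `n_bins` and `edges` (per-feature
#'   boundary vectors of length `n_bins + 1`).
#' @export
discretise_ewd <- function(matrix, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  m <- as.matrix(matrix)
  bins <- m
  edges <- vector("list", ncol(m))
  names(edges) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    if (hi <= lo) {
      bins[, j] <- 0L
      edges[[j]] <- seq(lo, lo + 1, length.out = n_bins + 1)
      next
    }
    width <- (hi - lo) / n_bins
    b <- floor((m[, j] - lo) / width)
    bins[, j] <- pmin.int(pmax.int(b, 0L), n_bins - 1L)
    edges[[j]] <- seq(lo, hi, length.out = n_bins + 1)
  }
  storage.mode(bins) <- "integer"
  structure(list(bins = bins, n_bins = n_bins, edges = edges),
            class = "har_discretised")
}
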