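# Time-domain feature block: basic statistics, autocorrelation,
# first principal component, geometry (Dxyz, SMA) and Burg AR(5)
# coefficients. Mean and standard deviation are computed on the raw
# channels; every other feature uses the filtered channels.

#' Mean, standard deviation and RMS per signal
#'
#' Means and standard deviations are taken from the raw channels (they
#' carry the gravity/orientation information the high-pass removes);
#' RMS is taken from the filtered channels and the magnitude channel.
#'
#' @param window one window from [segment_recording()].
#' @return Named numeric vector of 12 values
#'   (`mean_*`, `std_*`, `rms_*` over x, y, z, mg; the "raw" mg used for
#'   mean/std is the magnitude of the raw channels).
#' @export
basic_stats <- function(window) {
  stopifnot(length(window$x) >= 2)
  mg_raw <- sqrt(window$x^2 + window$y^2 + window$z^2)
  raw <- list(x = window$x, y = window$y, z = window$z, mg = mg_raw)
  filt <- list(x = window$xf, y = window$yf, z = window$zf, mg = window$mg)
  c(
    stats::setNames(vapply(raw, mean, numeric(1)), paste0("mean_", names(raw))),
    stats::setNames(vapply(raw, sd, numeric(1)), paste0("std_", names(raw))),
    stats::setNames(vapply(filt, function(v) sqrt(mean(v^2)), numeric(1)),
                    paste0("rms_", names(filt)))
  )
}

# Normalized autocorrelation of one channel at a single integer lag.
acf_at_lag <- function(v, lag) {
  n <- length(v)
  if (lag >= n) return(0)
  mv <- mean(v)
  denom <- sum((v - mv)^2)
  if (denom == 0) return(0)
  sum((v[1:(n - lag)] - mv) * (v[(lag + 1):n] - mv)) / denom
}

#' Autocorrelation features at fixed time lags
#'
#' Normalized autocorrelation of each filtered channel (and mg) at three
#' time-anchored lags, converted to samples by rounding so the features
#' are comparable across sampling frequencies. Zero-variance channels
#' yield 0 at every lag.
#'
#' @param window one window.
#' @param lags_s lags in seconds (default `c(0.2, 0.4, 0.6)`).
#' @return Named numeric vector of 12 values in `[-1, 1]`.
#' @export
autocorrelation_features <- function(window, lags_s = c(0.2, 0.4, 0.6)) {
  lags <- pmax(1L, round(lags_s * window$fs))
  if (max(lags) >= length(window$xf) / 2)
    stop("largest lag must be below half the window length")
  sigs <- list(x = window$xf, y = window$yf, z = window$zf, mg = window$mg)
  out <- numeric(0)
  for (s in names(sigs)) {
    vals <- vapply(lags, function(l) acf_at_lag(sigs[[s]], l), numeric(1))
    names(vals) <- paste0("acf", seq_along(lags), "_", s)
    out <- c(out, vals)
  }
  out
}

#' Maximum difference Dxyz and signal magnitude area
#'
#' `dxyz = sqrt(range(xf)^2 + range(yf)^2 + range(zf)^2)` combines the
#' per-axis peak-to-peak excursions; `sma` is the mean over samples of
#' `|xf| + |yf| + |zf|`, a standard activity-intensity measure.
#'
#' @param window one window.
#' @return Named numeric vector `c(dxyz, sma)`.
#' @export
geometry_features <- function(window) {
  stopifnot(length(window$xf) >= 1)
  rng <- function(v) diff(range(v))
  c(dxyz = sqrt(rng(window$xf)^2 + rng(window$yf)^2 + rng(window$zf)^2),
    sma = mean(abs(window$xf) + abs(window$yf) + abs(window$zf)))
}

#' Loadings of the first principal component of the (x, y, z) cloud
#'
#' Unit-norm eigenvector of the 3x3 covariance of the filtered channels
#' with the largest eigenvalue; the sign is fixed so the
#' largest-magnitude loading is positive. An all-zero window yields the
#' sentinel `(1, 0, 0)` with a warning.
#'
#' @param window one window.
#' @return Named numeric vector of 3 loadings with unit Euclidean norm.
#' @export
pca_pc1 <- function(window) {
  m <- cbind(window$xf, window$yf, window$zf)
  if (nrow(m) < 3) stop("need at least 3 samples for the principal component")
  if (all(m == 0)) {
    warning("all-zero window: principal component undefined, using (1, 0, 0)")
    return(c(pca_pc1_x = 1, pca_pc1_y = 0, pca_pc1_z = 0))
  }
  v <- eigen(cov(m), symmetric = TRUE)$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  c(pca_pc1_x = v[1], pca_pc1_y = v[2], pca_pc1_z = v[3])
}

#' Burg AR(5) coefficients and residual variance per signal
#'
#' Fits an order-5 autoregressive model to each filtered channel (and
#' mg) with the Burg method, which is stable on short windows. The sixth
#' value per signal is the residual (innovation) variance, so the block
#' totals 24 features. Zero-variance channels yield six zeros.
#'
#' @param window one window.
#' @param order AR order (default 5).
#' @return Named numeric vector of `4 * (order + 1)` values.
#' @export
ar_coefficients <- function(window, order = 5) {
  if (length(window$xf) <= 3 * order)
    stop("window too short for an AR model of order ", order)
  sigs <- list(x = window$xf, y = window$yf, z = window$zf, mg = window$mg)
  out <- numeric(0)
  for (s in names(sigs)) {
    v <- sigs[[s]]
    vals <- rep(0, order + 1)
    if (var(v) > 0) {
      fit <- tryCatch(ar.burg(v, aic = FALSE, order.max = order,
                              demean = TRUE),
                      error = function(e) NULL)
      if (!is.null(fit)) vals <- c(fit$ar, fit$var.pred)
    }
    names(vals) <- paste0(c(paste0("ar", seq_len(order)), "arvar"), "_", s)
    out <- c(out, vals)
  }
  out
}
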