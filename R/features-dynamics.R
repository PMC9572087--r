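# Repeatability/regularity feature block: recurrence quantification
# analysis (RR, DET, ENTR, L), permutation entropy and the largest
# Lyapunov exponent estimated with the Rosenstein small-data-quantity
# method.

#' Time-delay embedding of a scalar series
#'
#' Reconstructs `m`-dimensional phase-space states
#' `Y_j = (x_j, x_{j+tau}, ..., x_{j+(m-1)tau})`.
#'
#' @param series numeric vector with length `> (m - 1) * tau`.
#' @param m embedding dimension, `>= 1`.
#' @param tau lag in samples, `>= 1`.
#' @return Matrix with `length(series) - (m - 1) * tau` rows and `m`
#'   columns, one state per row.
#' @export
embed_series <- function(series, m, tau) {
  stopifnot(m >= 1, tau >= 1)
  N <- length(series) - (m - 1) * tau
  if (N < 1) stop("series too short for embedding: need length > (m-1)*tau")
  out <- vapply(0:(m - 1), function(j) series[(1:N) + j * tau],
                numeric(N))
  if (N == 1) out <- matrix(out, nrow = 1)
  out
}

#' Recurrence matrix of embedded states
#'
#' Binary matrix `R[i, j] = 1` when the Euclidean distance between
#' states `i` and `j` is at most `eps`. Symmetric with a unit main
#' diagonal.
#'
#' @param states state matrix from [embed_series()] (rows are states).
#' @param eps recurrence threshold, `> 0`, in signal units.
#' @return Integer 0/1 matrix, `N x N`.
#' @export
recurrence_matrix <- function(states, eps) {
  if (eps <= 0) stop("eps must be positive")
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  D <- as.matrix(dist(states))
  R <- (D <= eps) + 0L
  storage.mode(R) <- "integer"
  R
}

# Census of diagonal line lengths off the main diagonal (both
# triangles). Returns an integer vector of run lengths of consecutive
# recurrence points along each diagonal.
diagonal_lines <- function(R) {
  N <- nrow(R)
  lens <- integer(0)
  if (N < 2) return(lens)
  for (d in 1:(N - 1)) {
    v <- R[cbind(1:(N - d), (1 + d):N)]  # upper diagonal d
    r <- rle(v)
    runs <- r$lengths[r$values == 1L]
    if (length(runs)) lens <- c(lens, runs, runs)  # symmetric: lower too
  }
  lens
}

#' Recurrence quantification measures
#'
#' From a recurrence matrix computes the recurrence rate
#' `RR = sum(R) / N^2` (all entries, including the main diagonal), and
#' from the histogram `P(l)` of diagonal line lengths (main diagonal
#' excluded, both triangles counted): determinism
#' `DET = sum_{l >= lmin} l P(l) / sum_{l >= 1} l P(l)`, the Shannon
#' entropy `ENTR = -sum p(l) ln p(l)` with `p(l)` normalized over
#' `l >= lmin`, and the mean line length `L = sum l p(l)`. With no
#' off-diagonal recurrence points, DET, ENTR and L are defined as 0.
#'
#' @param R recurrence matrix from [recurrence_matrix()].
#' @param lmin minimal diagonal line length counted as deterministic
#'   (default 2).
#' @return Named list `rr`, `det`, `entr`, `l_mean`.
#' @export
rqa <- function(R, lmin = 2) {
  N <- nrow(R)
  rr <- sum(R) / N^2
  lens <- diagonal_lines(R)
  if (!length(lens) || !any(lens >= lmin))
    return(list(rr = rr, det = 0, entr = 0, l_mean = 0))
  det <- sum(lens[lens >= lmin]) / sum(lens)
  keep <- lens[lens >= lmin]
  tab <- table(keep)
  p <- as.numeric(tab) / length(keep)
  entr <- -sum(p * log(p))
  l_mean <- sum(as.numeric(names(tab)) * p)
  list(rr = rr, det = det, entr = entr, l_mean = l_mean)
}

#' Permutation entropy of a time series
#'
#' Shannon entropy (natural log) of the empirical distribution of
#' ordinal patterns: each length-`n` delay vector is encoded by the rank
#' order of its values, ties broken by order of occurrence (stable
#' rank). A strictly monotone series has a single pattern and entropy 0;
#' white noise approaches `ln(n!)`.
#'
#' @param series numeric vector of length `>= n! + n`.
#' @param n pattern order (default 3).
#' @param delay lag between pattern elements in samples (default 1).
#' @return Entropy in nats, in `[0, ln(n!)]`.
#' @export
permutation_entropy <- function(series, n = 3, delay = 1) {
  stopifnot(n >= 2, delay >= 1)
  if (length(series) < factorial(n) + n)
    stop("series too short: need at least n! + n = ", factorial(n) + n,
         " samples")
  Y <- embed_series(series, n, delay)
  codes <- apply(Y, 1L, function(v) {
    paste(order(v), collapse = "")  # stable: ties by position
  })
  p <- table(codes) / length(codes)
  -sum(p * log(p))
}

#' Largest Lyapunov exponent (Rosenstein small-data method)
#'
#' Embeds the series, pairs every reference state with its nearest
#' neighbour outside a temporal exclusion window (one dominant period,
#' estimated from the spectral peak), and tracks the mean log2 distance
#' between the pairs over time. The exponent is the least-squares slope
#' of the initial linear region of the divergence curve, multiplied by
#' `fs` to give log2 units per unit time (per step when `fs = 1`). The
#' fit stops before the curve saturates at the attractor size (at 70% of
#' the rise toward the plateau, capped at one tenth of the number of
#' states). Positive values indicate chaotic divergence; periodic
#' signals give values near 0.
#'
#' @param series numeric vector of length `>= 50`.
#' @param m embedding dimension (default 3).
#' @param tau embedding lag in samples (default 1).
#' @param fs sampling frequency (use 1 for exponent per step).
#' @return Scalar exponent in log2 units per time; 0 (with a warning)
#'   when no valid neighbour pairs exist or the series is constant.
#' @export
largest_lyapunov <- function(series, m = 3, tau = 1, fs = 1) {
  if (length(series) < 50)
    stop("series too short for a Lyapunov estimate: need at least 50 samples")
  if (var(series) == 0) {
    warning("constant series: Lyapunov exponent defined as 0")
    return(0)
  }
  Y <- embed_series(series, m, tau)
  N <- nrow(Y)
  # temporal exclusion: one dominant period (spectral-peak read-off)
  xc <- series - mean(series)
  sp <- Mod(fft(xc))[2:max(2, floor(length(series) / 2))]
  period <- length(series) / which.max(sp)
  theiler <- max(1L, round(min(period, N / 10)))
  D <- as.matrix(dist(Y))
  D[abs(row(D) - col(D)) <= theiler] <- Inf
  nn <- apply(D, 1L, which.min)
  valid <- is.finite(D[cbind(seq_len(N), nn)])
  if (!any(valid)) {
    warning("no valid neighbour pairs; Lyapunov exponent defined as 0")
    return(0)
  }
  kmax <- max(3L, floor(N / 10))
  y <- rep(NA_real_, kmax + 1L)
  for (k in 0:kmax) {
    i <- which(valid & (seq_len(N) + k) <= N & (nn + k) <= N)
    if (!length(i)) break
    d <- sqrt(rowSums((Y[i + k, , drop = FALSE] -
                         Y[nn[i] + k, , drop = FALSE])^2))
    y[k + 1L] <- mean(log2(pmax(d, 1e-12)))
  }
  y <- y[!is.na(y)]
  if (length(y) < 3) return(0)
  y0 <- y[1]; ysat <- max(y)
  if (ysat - y0 < 1e-9) return(0)  # flat divergence curve
  K <- which(y >= y0 + 0.7 * (ysat - y0))[1]
  K <- min(max(K, 3L), length(y))
  ks <- seq_along(y) - 1L
  fit <- lm(y[2:K] ~ ks[2:K])
  unname(coef(fit)[2]) * fs
}

#' All repeatability/regularity features of one window
#'
#' RQA (RR, DET, ENTR, L), the largest Lyapunov exponent and permutation
#' entropy for each filtered channel and the magnitude channel: 24
#' scalars. The recurrence threshold is adaptive per signal:
#' `eps_fraction` times the maximum phase-space distance in the window,
#' which keeps the recurrence rate usable across amplitudes.
#'
#' @param window one window from [segment_recording()].
#' @param m,tau embedding parameters (defaults 3 and 1; short 2.5 s
#'   windows cannot support large `(m - 1) * tau` products at 20 Hz).
#' @param eps_fraction recurrence threshold as a fraction of the maximal
#'   state distance (default 0.2).
#' @param lmin minimal diagonal line length (default 2).
#' @param pe_order,pe_delay permutation-entropy parameters (defaults 3, 1).
#' @return Named numeric vector of 24 values.
#' @export
dynamics_features <- function(window, m = 3, tau = 1, eps_fraction = 0.2,
                              lmin = 2, pe_order = 3, pe_delay = 1) {
  sigs <- list(x = window$xf, y = window$yf, z = window$zf, mg = window$mg)
  out <- numeric(0)
  for (s in names(sigs)) {
    v <- sigs[[s]]
    if (var(v) == 0) {
      vals <- c(1, 0, 0, 0, 0, 0)  # constant: full recurrence, no structure
    } else {
      Y <- embed_series(v, m, tau)
      D <- as.matrix(dist(Y))
      eps <- eps_fraction * max(D)
      R <- (D <= eps) + 0L
      q <- rqa(R, lmin)
      lam <- suppressWarnings(largest_lyapunov(v, m, tau, fs = 1))
      pe <- permutation_entropy(v, pe_order, pe_delay)
      vals <- c(q$rr, q$det, q$entr, q$l_mean, lam, pe)
    }
    names(vals) <- paste0(c("rqa_rr", "rqa_det", "rqa_entr", "rqa_l",
                            "lle", "pe"), "_", s)
    out <- c(out, vals)
  }
  out
}
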