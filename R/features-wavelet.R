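# Time-frequency feature block: 5-level wavelet packet decomposition
# (WPD) with an orthonormal Daubechies filter bank. The transform uses
# circular convolution on a signal zero-padded to a multiple of
# 2^levels, which makes the analysis exactly orthogonal: terminal-node
# energies sum to the signal energy to machine precision.

# Orthonormal Daubechies-4 analysis pair (8 taps) and the
# quadrature-mirror high-pass derived from it.
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- rev(DB4_LO) * c(1, -1)

HAAR_LO <- c(1, 1) / sqrt(2)
HAAR_HI <- c(1, -1) / sqrt(2)

wpd_filters <- function(wavelet) {
  switch(wavelet,
         db4 = list(lo = DB4_LO, hi = DB4_HI),
         haar = list(lo = HAAR_LO, hi = HAAR_HI),
         stop("unknown wavelet: ", wavelet, " (available: db4, haar)"))
}

# one analysis step: circular convolution + dyadic downsampling
wp_step <- function(x, filt) {
  N <- length(x)
  L <- length(filt)
  half <- N %/% 2L
  out <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% N) + 1L
    out[k] <- sum(filt * x[idx])
  }
  out
}

#' Wavelet packet decomposition to a fixed depth
#'
#' Builds the full packet tree: both the approximation and the detail
#' band are re-split at every level, giving `2^levels` terminal nodes
#' that tile `(0, fs/2]` in equal-width bands. Nodes are
#' frequency-ordered (Gray-code reordering corrects the band inversion
#' that dyadic downsampling introduces in high-pass branches), so node
#' `f` at the terminal level covers approximately
#' `(f, f + 1] * fs / 2^(levels+1)` Hz. Signals whose length is not a
#' multiple of `2^levels` are zero-padded up to the next multiple, which
#' leaves the total energy unchanged.
#'
#' @param signal numeric vector of length `>= 2^levels`.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param levels decomposition depth (default 5).
#' @return An object of class `har_wpd`: list with `nodes` (terminal
#'   coefficient vectors, frequency order), `freq_index`, `levels`,
#'   `wavelet`.
#' @export
#' @examples
#' x <- rnorm(128)
#' tr <- wpd_decompose(x)
#' # orthogonality: terminal-node energies reproduce the signal energy
#' abs(sum(sapply(tr$nodes, function(cf) sum(cf^2))) - sum(x^2))
wpd_decompose <- function(signal, wavelet = "db4", levels = 5) {
  n_min <- 2^levels
  if (length(signal) < n_min)
    stop("signal too short for ", levels, "-level decomposition: need at least ",
         n_min, " samples, got ", length(signal))
  filt <- wpd_filters(wavelet)
  pad <- (n_min - length(signal) %% n_min) %% n_min
  x <- c(signal, numeric(pad))
  nodes <- list(list(coef = x, freq = 0L))
  for (lev in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      a <- wp_step(nd$coef, filt$lo)
      d <- wp_step(nd$coef, filt$hi)
      if (nd$freq %% 2L == 0L) {
        nxt[[2L * i - 1L]] <- list(coef = a, freq = 2L * nd$freq)
        nxt[[2L * i]]      <- list(coef = d, freq = 2L * nd$freq + 1L)
      } else {
        nxt[[2L * i - 1L]] <- list(coef = a, freq = 2L * nd$freq + 1L)
        nxt[[2L * i]]      <- list(coef = d, freq = 2L * nd$freq)
      }
    }
    nodes <- nxt
  }
  fr <- vapply(nodes, `[[`, integer(1), "freq")
  ord <- order(fr)
  structure(list(nodes = lapply(nodes[ord], `[[`, "coef"),
                 freq_index = fr[ord], levels = levels, wavelet = wavelet),
            class = "har_wpd")
}

#' WPD features of the targeted low-frequency nodes
#'
#' For each of the `n_nodes` lowest-frequency terminal nodes (covering
#' `(0, n_nodes * fs / 2^(levels+1)]` Hz, the band where locomotion
#' energy concentrates) computes three statistics of the coefficients:
#' the sum of absolute values, the energy (sum of squares) and the
#' Shannon entropy (natural log) of the normalized squared coefficients.
#' An all-zero node has entropy 0.
#'
#' @param tree a `har_wpd` object from [wpd_decompose()].
#' @param n_nodes number of targeted lowest-frequency nodes (default 3).
#' @return Named numeric vector of `3 * n_nodes` values
#'   (`wpd_n<i>_sumabs`, `wpd_n<i>_energy`, `wpd_n<i>_entropy`).
#' @export
wpd_features <- function(tree, n_nodes = 3) {
  stopifnot(inherits(tree, "har_wpd"))
  out <- numeric(0)
  for (i in seq_len(n_nodes)) {
    cf <- tree$nodes[[i]]
    en <- sum(cf^2)
    ent <- 0
    if (en > 0) {
      p <- cf^2 / en
      p <- p[p > 0]
      ent <- -sum(p * log(p))
    }
    v <- c(sum(abs(cf)), en, ent)
    names(v) <- paste0("wpd_n", i, "_", c("sumabs", "energy", "entropy"))
    out <- c(out, v)
  }
  out
}
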