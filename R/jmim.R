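# Discrete mutual-information estimation (plug-in, natural log) and the
# JMIM greedy forward selection: starting from the single feature with
# maximal MI with the class, repeatedly add the candidate that maximises
# the minimum over selected features of I((f_candidate, f_selected); C).

# Map an arbitrary discrete vector to integer codes 1..K.
as_codes <- function(v) {
  if (is.factor(v)) return(list(codes = as.integer(v), k = nlevels(v)))
  u <- sort(unique(v))
  list(codes = match(v, u), k = length(u))
}

# MI in nats between two integer-coded vectors (codes in 1..ka, 1..kb),
# via tabulate() for speed.
mi_codes <- function(a, ka, b, kb) {
  n <- length(a)
  joint <- tabulate((a - 1L) * kb + b, nbins = ka * kb)
  pa <- tabulate(a, nbins = ka) / n
  pb <- tabulate(b, nbins = kb) / n
  nz <- which(joint > 0L)
  pj <- joint[nz] / n
  ia <- ((nz - 1L) %/% kb) + 1L
  ib <- ((nz - 1L) %% kb) + 1L
  sum(pj * log(pj / (pa[ia] * pb[ib])))
}

#' Mutual information between two discrete variables
#'
#' Plug-in (empirical histogram) estimate in nats.
#'
#' @param a,b vectors of equal length (integer, character or factor).
#' @return Non-negative scalar, nats.
#' @export
#' @examples
#' x <- rep(0:1, 50)
#' mutual_information(x, x)  # H(X) = ln 2
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ca <- as_codes(a); cb <- as_codes(b)
  mi_codes(ca$codes, ca$k, cb$codes, cb$k)
}

#' Joint mutual information of a feature pair with the class
#'
#' `I((fi, fs); C)`: the pair is treated as a single variable via
#' product coding. Always at least `max(I(fi; C), I(fs; C))` on exact
#' tables.
#'
#' @param fi,fs discrete feature vectors.
#' @param c class vector of the same length.
#' @return Non-negative scalar, nats.
#' @export
joint_mutual_information <- function(fi, fs, c) {
  if (length(fi) != length(fs) || length(fi) != length(c))
    stop("fi, fs and c must have equal length")
  ci <- as_codes(fi); cs <- as_codes(fs); cc <- as_codes(c)
  pair <- (ci$codes - 1L) * cs$k + cs$codes
  mi_codes(pair, ci$k * cs$k, cc$codes, cc$k)
}

#' JMIM greedy forward feature selection
#'
#' Implements the forward greedy search: (1) compute `I(C; fi)` for all
#' features; (2) select the feature maximising it; (3) repeatedly add
#' the candidate `fi` maximising
#' `min over selected fs of I((fi, fs); C)` until `k` features are
#' selected. Ties are broken deterministically by the lowest feature
#' index.
#'
#' @param D a `har_discretised` object from [discretise_ewd()], or an
#'   integer matrix of discretised features (windows x features).
#' @param labels class label per window (factor or character).
#' @param k number of features to select (default: all, giving the full
#'   ranking that drives the incremental evaluation curve).
#' @return An object of class `har_ranking`: list with `order` (selected
#'   feature indices, selection order), `scores` (goal-function value at
#'   each step; the first entry is `I(C; f_first)`), `feature_names`.
#' @export
jmim_select <- function(D, labels, k = NULL) {
  bins <- if (inherits(D, "har_discretised")) D$bins else as.matrix(D)
  p <- ncol(bins)
  n <- nrow(bins)
  if (length(labels) != n) stop("labels must match the number of windows")
  if (is.null(k)) k <- p
  if (k < 1 || k > p) stop("k must lie between 1 and the number of features")
  cl <- as_codes(labels)
  cols <- lapply(seq_len(p), function(j) as_codes(bins[, j]))
  relevance <- vapply(seq_len(p), function(j)
    mi_codes(cols[[j]]$codes, cols[[j]]$k, cl$codes, cl$k), numeric(1))
  # ties (within numerical noise) break to the lowest feature index
  argmax_lowest <- function(v, idx) idx[which(v >= max(v) - 1e-9)[1]]
  first <- argmax_lowest(relevance, seq_len(p))
  order_sel <- integer(k)
  scores <- numeric(k)
  order_sel[1] <- first
  scores[1] <- relevance[first]
  remaining <- setdiff(seq_len(p), first)
  # running min over selected features of I((fi, fs); C) per candidate
  minjoint <- rep(Inf, p)
  last_added <- first
  step <- 1L
  while (step < k) {
    fs <- cols[[last_added]]
    for (j in remaining) {
      fi <- cols[[j]]
      pair <- (fi$codes - 1L) * fs$k + fs$codes
      jm <- mi_codes(pair, fi$k * fs$k, cl$codes, cl$k)
      if (jm < minjoint[j]) minjoint[j] <- jm
    }
    best <- argmax_lowest(minjoint[remaining], remaining)
    step <- step + 1L
    order_sel[step] <- best
    scores[step] <- minjoint[best]
    remaining <- setdiff(remaining, best)
    last_added <- best
  }
  structure(list(order = order_sel, scores = scores,
                 feature_names = colnames(bins) %||%
                   paste0("f", seq_len(p))),
            class = "har_ranking")
}

#' @export
print.har_ranking <- function(x, ...) {
  cat(sprintf("<har_ranking> %d features selected\n", length(x$order)))
  top <- head(seq_along(x$order), 5L)
  cat("  top:", paste(sprintf("%s (%.3f)",
                              x$feature_names[x$order[top]],
                              x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Ranking as a data.frame
#'
#' @param x a `har_ranking`.
#' @param ... unused.
#' @return data.frame with columns `rank`, `feature_name`, `score`.
#' @export
as.data.frame.har_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$order),
             feature_name = x$feature_names[x$order],
             score = x$scores, stringsAsFactors = FALSE)
}
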