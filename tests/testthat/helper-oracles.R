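# Independent brute-force oracles, written against the definitions
# rather than the package implementations, plus small data helpers.

# Plain window constructor for unit tests of single feature blocks:
# the "filtered" channels are taken verbatim so expectations can be
# stated on the exact input vectors.
as_window <- function(x, y = rep(0, length(x)), z = rep(0, length(x)),
                      fs = 50, label = "a") {
  list(x = x, y = y, z = z, xf = x, yf = y, zf = z,
       mg = sqrt(x^2 + y^2 + z^2), label = label, fs = fs)
}

logistic_series <- function(n, x0 = 0.34, burn = 200) {
  x <- numeric(n + burn)
  x[1] <- x0
  for (i in seq_len(n + burn - 1)) x[i + 1] <- 4 * x[i] * (1 - x[i])
  x[(burn + 1):(burn + n)]
}

# Mutual information by explicit double loop over the joint table.
bf_mutual_information <- function(a, b) {
  ja <- factor(a); jb <- factor(b)
  n <- length(a)
  out <- 0
  for (u in levels(ja)) for (v in levels(jb)) {
    pxy <- sum(ja == u & jb == v) / n
    if (pxy > 0) {
      px <- sum(ja == u) / n
      py <- sum(jb == v) / n
      out <- out + pxy * log(pxy / (px * py))
    }
  }
  out
}

# Greedy JMIM by direct restatement: at every step recompute, for each
# candidate, the minimum over ALL selected features of the joint MI of
# the pair-coded variable with the class.
bf_jmim <- function(bins, labels, k = ncol(bins)) {
  p <- ncol(bins)
  # ties within numerical noise break to the lowest feature index
  pick <- function(v, idx) idx[which(v >= max(v) - 1e-9)[1]]
  rel <- sapply(seq_len(p), function(j) bf_mutual_information(bins[, j], labels))
  sel <- pick(rel, seq_len(p))
  while (length(sel) < k) {
    cand <- setdiff(seq_len(p), sel)
    goal <- sapply(cand, function(j) {
      min(sapply(sel, function(s)
        bf_mutual_information(paste(bins[, j], bins[, s]), labels)))
    })
    sel <- c(sel, pick(goal, cand))
  }
  sel
}

# Diagonal-line census by scanning every diagonal of both triangles
# element by element (no rle), returning all run lengths.
bf_diagonal_lines <- function(R) {
  N <- nrow(R)
  lens <- integer(0)
  for (d in c(-(N - 1):-1, 1:(N - 1))) {
    run <- 0L
    for (i in seq_len(N)) {
      j <- i + d
      if (j < 1 || j > N) next
      if (R[i, j] == 1L) run <- run + 1L
      else {
        if (run > 0L) lens <- c(lens, run)
        run <- 0L
      }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

bf_rqa <- function(R, lmin = 2) {
  rr <- 0
  N <- nrow(R)
  for (i in seq_len(N)) for (j in seq_len(N)) rr <- rr + R[i, j]
  rr <- rr / N^2
  lens <- bf_diagonal_lines(R)
  if (!length(lens) || !any(lens >= lmin))
    return(list(rr = rr, det = 0, entr = 0, l_mean = 0))
  det <- sum(lens[lens >= lmin]) / sum(lens)
  keep <- lens[lens >= lmin]
  p <- table(keep) / length(keep)
  list(rr = rr, det = det, entr = -sum(p * log(p)),
       l_mean = sum(as.numeric(names(p)) * p))
}

# Macro metrics by an explicit one-vs-rest loop.
bf_macro_metrics <- function(cm) {
  M <- nrow(cm)
  total <- sum(cm)
  acc <- prec <- rec <- 0
  for (i in seq_len(M)) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    acc <- acc + (tp + tn) / (tp + tn + fp + fn)
    if (tp + fp > 0) prec <- prec + tp / (tp + fp)
    if (tp + fn > 0) rec <- rec + tp / (tp + fn)
  }
  prec <- prec / M; rec <- rec / M
  list(accuracy_macro = acc / M, precision = prec, recall = rec,
       f_measure = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}
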