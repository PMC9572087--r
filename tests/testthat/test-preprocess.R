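test_that("segmentation yields the expected window counts and labels", {
  # 5 s at 20 Hz, 2.5 s sequential windows -> two occurrences
  rec <- har_recording(x = sin(2 * pi * 2 * (0:99) / 20),
                       y = rnorm(100, sd = 0.01), z = rep(1, 100),
                       label = "walk", fs = 20)
  expect_length(segment_recording(rec), 2L)

  # shorter than one window -> empty, not an error
  short <- har_recording(x = rnorm(48), y = rnorm(48), z = rnorm(48),
                         label = "sit", fs = 20)
  expect_length(segment_recording(short), 0L)

  # 10 s at 20 Hz, 50% overlap: step 25 -> floor((200 - 50)/25) + 1 = 7
  long <- har_recording(x = rnorm(200), y = rnorm(200), z = rnorm(200),
                        label = "sit", fs = 20)
  expect_length(segment_recording(long, overlap_fraction = 0.5), 7L)

  # modal label with deterministic first-encountered tie-break
  lab <- c(rep("a", 25), rep("b", 25), rep("a", 50))
  rec2 <- har_recording(x = rnorm(100), y = rnorm(100), z = rnorm(100),
                        label = lab, fs = 20)
  w <- segment_recording(rec2)
  expect_equal(as.character(attr(w, "labels")), c("a", "a"))
  tied <- modal_label(factor(c("b", "a", "b", "a")))
  expect_equal(tied, "b")
})

test_that("segmentation with no overlap conserves sample coverage", {
  for (n in c(137, 200, 251)) {
    rec <- har_recording(x = rnorm(n), y = rnorm(n), z = rnorm(n),
                         label = "s", fs = 20)
    w <- segment_recording(rec)
    covered <- length(w) * 50
    expect_lte(covered, n)
    expect_lt(n, covered + 50)
  }
})

test_that("irregular timestamps are rejected", {
  t <- (0:99) / 20
  t[50] <- t[50] + 0.03  # 60% of a sample interval
  rec <- har_recording(x = rnorm(100), y = rnorm(100), z = rnorm(100),
                       label = "s", fs = 20, time = t)
  expect_error(segment_recording(rec), "irregular sampling")
})

test_that("high-pass filter removes DC and preserves the gait band", {
  expect_equal(highpass(rep(0, 100), fs = 50), rep(0, 100))

  const <- rep(9.81, 200)
  expect_lt(max(abs(highpass(const, fs = 50))), 1e-6 * 9.81)

  # DC + 2 Hz unit sine: passband amplitude within 5% (read via FFT bin)
  fs <- 50; n <- 500
  t <- (0:(n - 1)) / fs
  x <- 3 + sin(2 * pi * 2 * t)  # 2 Hz aligns with bin 21
  xf <- highpass(x, fs, cutoff = 0.5)
  amp <- Mod(fft(xf))[2 * n / fs + 1] * 2 / n
  expect_lt(abs(amp - 1), 0.05)

  expect_error(highpass(rnorm(100), fs = 50, cutoff = 25), "Nyquist")
})

test_that("high-pass filtering is approximately idempotent in-band", {
  fs <- 50
  t <- (0:499) / fs
  for (x in list(sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t),
                 sin(2 * pi * 1.8 * t) + 0.3 * sin(2 * pi * 3.6 * t))) {
    once <- highpass(x, fs)
    twice <- highpass(once, fs)
    d <- abs(twice - once)
    rms <- sqrt(mean(once^2))
    # residual change concentrates in the filter settle region at the
    # edges (a few time constants, tau = fs / (2 pi cutoff) ~ 16 samples)
    interior <- 50:450
    expect_lt(max(d[interior]), 0.05 * rms)
    expect_lt(sqrt(mean(d^2)), 0.05 * rms)
  }
})

test_that("window magnitude is rotation invariant and non-negative", {
  set.seed(1)
  n <- 200
  x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
  rec <- har_recording(x, y, z, "s", fs = 50)
  # rotation about an arbitrary axis
  th <- 0.73
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- cbind(x, y, z) %*% t(Rz)
  rec2 <- har_recording(rot[, 1], rot[, 2], rot[, 3], "s", fs = 50)
  w1 <- segment_recording(rec)
  w2 <- segment_recording(rec2)
  for (i in seq_along(w1)) {
    expect_true(all(w1[[i]]$mg >= 0))
    expect_lt(max(abs(w1[[i]]$mg - w2[[i]]$mg)), 1e-9)
  }
})

test_that("feature normalization standardizes columns and zeroes degenerate ones", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 0, 2))
  out <- normalize_features(m)
  expect_equal(out[, "a"], c(-1, 0, 1), ignore_attr = TRUE)  # sample sd = 1
  expect_equal(colMeans(out), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(out, 2, sd), c(a = 1, b = 1), tolerance = 1e-9)

  mc <- cbind(a = rnorm(10), b = rep(7, 10))
  expect_warning(outc <- normalize_features(mc), "zero-variance")
  expect_equal(outc[, "b"], rep(0, 10), ignore_attr = TRUE)
})

test_that("equal-width discretisation maps ranges to the stated bins", {
  v <- c(0, 2.5, 5, 7.3, 9.999)
  d <- discretise_ewd(cbind(f = v), n_bins = 5)
  expect_equal(d$edges$f, seq(0, 9.999, length.out = 6))
  # value 7.3 with range [0, 10): bin 3
  expect_equal(d$bins[4, "f"], 3L, ignore_attr = TRUE)
  expect_equal(d$bins[1, "f"], 0L, ignore_attr = TRUE)       # min -> 0
  expect_equal(d$bins[5, "f"], 4L, ignore_attr = TRUE)       # max -> n_bins - 1

  dc <- discretise_ewd(cbind(f = rep(3, 8)), n_bins = 10)
  expect_true(all(dc$bins == 0L))
})

test_that("every discretised value lies inside its assigned bin's edges", {
  set.seed(2)
  m <- cbind(a = rnorm(100), b = runif(100, -5, 12))
  d <- discretise_ewd(m, n_bins = 7)
  for (j in colnames(m)) {
    e <- d$edges[[j]]
    for (i in seq_len(nrow(m))) {
      b <- d$bins[i, j]
      expect_gte(m[i, j], e[b + 1] - 1e-12)
      expect_lte(m[i, j], e[b + 2] + 1e-12)
    }
  }
})
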