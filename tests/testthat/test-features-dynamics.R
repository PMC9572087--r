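test_that("time-delay embedding has the stated shape and content", {
  e <- embed_series(1:10, m = 3, tau = 1)
  expect_equal(dim(e), c(8L, 3L))

  e1 <- embed_series(c(4, 7, 1), m = 1, tau = 1)
  expect_equal(as.numeric(e1), c(4, 7, 1))

  e2 <- embed_series(1:6, m = 2, tau = 2)
  expect_equal(unname(e2), cbind(c(1, 2, 3, 4), c(3, 4, 5, 6)),
               ignore_attr = TRUE)

  expect_error(embed_series(1:4, m = 3, tau = 2), "too short")
})

test_that("recurrence matrix is symmetric, binary, unit diagonal", {
  R <- recurrence_matrix(embed_series(rep(2, 20), 3, 1), eps = 0.1)
  expect_true(all(R == 1L))  # constant series: zero distances

  st <- rbind(c(0, 0), c(10, 10))
  R2 <- recurrence_matrix(st, eps = 1)
  expect_equal(R2[1, 2], 0L)
  expect_equal(diag(R2), c(1L, 1L), ignore_attr = TRUE)

  set.seed(15)
  R3 <- recurrence_matrix(embed_series(rnorm(40), 3, 1), eps = 0.5)
  expect_equal(R3, t(R3))
  expect_true(all(R3 %in% c(0L, 1L)))
  expect_error(recurrence_matrix(st, eps = 0), "positive")
})

test_that("RQA measures match a brute-force diagonal census", {
  # rr equals the plain mean of R, including the main diagonal
  set.seed(16)
  for (i in 1:8) {
    R <- matrix(rbinom(30 * 30, 1, runif(1, 0.1, 0.5)), 30, 30)
    R <- (R | t(R)) + 0L
    diag(R) <- 1L
    got <- rqa(R, lmin = 2)
    want <- bf_rqa(R, lmin = 2)
    expect_equal(got$rr, want$rr, tolerance = 1e-12)
    expect_equal(got$det, want$det, tolerance = 1e-12)
    expect_equal(got$entr, want$entr, tolerance = 1e-12)
    expect_equal(got$l_mean, want$l_mean, tolerance = 1e-12)
    expect_equal(got$rr, mean(R), tolerance = 1e-12)
  }
})

test_that("RQA degenerate cases follow the stated definitions", {
  # all-ones matrix: full recurrence
  R1 <- matrix(1L, 15, 15)
  expect_equal(rqa(R1)$rr, 1)

  # identity matrix: no off-diagonal lines
  Ri <- diag(15L)
  q <- rqa(Ri)
  expect_equal(c(q$det, q$entr, q$l_mean), c(0, 0, 0))

  # all off-diagonal lines of one identical length -> ENTR = 0
  R <- diag(8L)
  R[cbind(1:3, 3:5)] <- 1L; R[cbind(3:5, 1:3)] <- 1L
  expect_equal(rqa(R)$entr, 0)
})

test_that("determinism separates periodic from stochastic signals", {
  set.seed(17)
  x <- sin(2 * pi * 2 * (0:199) / 50)  # 8 periods
  Ys <- embed_series(x, 3, 1)
  Ds <- as.matrix(dist(Ys))
  det_sine <- rqa((Ds <= 0.2 * max(Ds)) + 0L)$det

  nn <- rnorm(200, sd = sd(x))
  Yn <- embed_series(nn, 3, 1)
  Dn <- as.matrix(dist(Yn))
  det_noise <- rqa((Dn <= 0.2 * max(Dn)) + 0L)$det

  expect_gt(det_sine, 0.9)
  expect_gt(det_sine, det_noise)
})

test_that("permutation entropy matches pattern-counting references", {
  expect_equal(permutation_entropy(1:50, n = 3), 0)  # single pattern

  alt <- rep(c(1, 2), 25)[1:49]  # 48 patterns, up/down equally frequent
  expect_equal(permutation_entropy(alt, n = 2), log(2), tolerance = 1e-12)

  set.seed(18)
  pe <- permutation_entropy(runif(3000), n = 3)
  expect_lt(abs(pe - log(6)) / log(6), 0.05)

  expect_error(permutation_entropy(1:5, n = 3), "too short")
})

test_that("permutation entropy is invariant under monotone transforms", {
  set.seed(19)
  x <- cumsum(rnorm(300))
  x <- x - min(x) + 1
  pe0 <- permutation_entropy(x, 3)
  expect_equal(permutation_entropy(exp(x / max(x)), 3), pe0, tolerance = 1e-12)
  expect_equal(permutation_entropy(log(x), 3), pe0, tolerance = 1e-12)
  expect_equal(permutation_entropy(3 * x + 11, 3), pe0, tolerance = 1e-12)
})

test_that("largest Lyapunov exponent recovers analytic references", {
  x <- logistic_series(1000)
  lam <- largest_lyapunov(x, m = 3, tau = 1, fs = 1)
  expect_lt(abs(lam - 1), 0.15)  # ln 2 nats = 1 bit per step

  s <- sin(2 * pi * 2 * (0:999) / 50)
  expect_lte(abs(largest_lyapunov(s, 3, 1, 1)), 0.05)

  # duplicated halves give zero-distance neighbours; the distance floor
  # must keep the estimate finite
  dup <- rep(sin(2 * pi * 2 * (0:99) / 50) + 0.01 * (1:100), 2)
  expect_true(is.finite(largest_lyapunov(dup, 3, 1, 1)))

  expect_error(largest_lyapunov(rnorm(20), 3, 1, 1), "at least 50")
  expect_warning(lz <- largest_lyapunov(rep(1, 100), 3, 1, 1), "constant")
  expect_equal(lz, 0)
})

test_that("Lyapunov estimate is amplitude invariant", {
  x <- logistic_series(800, x0 = 0.41)
  l1 <- largest_lyapunov(x, 3, 1, 1)
  l2 <- largest_lyapunov(10 * x, 3, 1, 1)
  expect_lt(abs(l2 - l1) / abs(l1), 0.05)
})

test_that("dynamics block returns 24 features with sentinel handling", {
  set.seed(20)
  w <- as_window(rnorm(125), rnorm(125), rep(0.5, 125), fs = 50)
  d <- dynamics_features(w)
  expect_length(d, 24L)
  expect_true(all(is.finite(d)))
  # constant z channel: full recurrence sentinel
  expect_equal(unname(d["rqa_rr_z"]), 1)
  expect_equal(unname(d["pe_z"]), 0)
  expect_true(all(d[grepl("rqa_rr", names(d))] >= 0 &
                    d[grepl("rqa_rr", names(d))] <= 1))
  expect_true(all(d[grepl("rqa_det", names(d))] >= 0 &
                    d[grepl("rqa_det", names(d))] <= 1))
})
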