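test_that("generation is reproducible and respects durations", {
  specs <- default_activity_specs(duration = 10)
  r1 <- generate_recording(specs, fs = 50, seed = 9)
  r2 <- generate_recording(specs, fs = 50, seed = 9)
  expect_identical(r1, r2)
  r3 <- generate_recording(specs, fs = 50, seed = 10)
  expect_false(identical(r1$x, r3$x))

  expect_equal(length(r1$x), 4 * 10 * 50)
  expect_equal(as.numeric(table(r1$label)), rep(500, 4))

  bad <- activity_spec("fast", "periodic", cadence = 20, amplitude = c(1, 1, 1))
  expect_error(generate_recording(list(bad), fs = 50), "Nyquist")
})

test_that("periodic windows have higher filtered RMS and DET than static ones", {
  specs <- list(
    activity_spec("sit", "static", noise_sd = 0.05, duration = 80),
    activity_spec("walk", "periodic", cadence = 2, amplitude = c(0.3, 0.2, 0.4),
                  noise_sd = 0.05, duration = 80)
  )
  rec <- generate_recording(specs, fs = 50, seed = 11)
  w <- segment_recording(rec)
  lab <- attr(w, "labels")
  expect_gte(min(table(lab)), 30)
  rms <- vapply(w, function(win) sqrt(mean(win$mg^2)), numeric(1))
  det <- vapply(w, function(win) {
    Y <- embed_series(win$xf, 3, 1)
    D <- as.matrix(dist(Y))
    rqa((D <= 0.2 * max(D)) + 0L)$det
  }, numeric(1))
  expect_gt(mean(rms[lab == "walk"]), mean(rms[lab == "sit"]))
  expect_gt(mean(det[lab == "walk"]), mean(det[lab == "sit"]))
})

test_that("class separability scales with amplitude separation", {
  run_level <- function(scale) {
    specs <- list(
      activity_spec("a", "periodic", cadence = 1.63,
                    amplitude = c(0.3, 0.3, 0.3), noise_sd = 0.1,
                    duration = 25),
      activity_spec("b", "periodic", cadence = 1.63,
                    amplitude = c(0.3, 0.3, 0.3) * (1 + scale),
                    noise_sd = 0.1, duration = 25)
    )
    rec <- generate_recording(specs, fs = 50, seed = 12)
    w <- segment_recording(rec)
    ft <- suppressMessages(extract_features(w))
    nf <- suppressWarnings(normalize_features(ft))
    rk <- jmim_select(discretise_ewd(nf, 10), attr(ft, "labels"))
    cv <- cross_validate(nf, rk, subset_sizes = 20, classifiers = "svm",
                         folds = 5, seed = 13, labels = attr(ft, "labels"))
    cv$f_measure
  }
  f <- vapply(c(0, 0.5, 2), run_level, numeric(1))
  # identical specs: near two-class chance; then monotone improvement
  expect_lt(f[1], 0.75)
  expect_lte(f[1], f[2])
  expect_lte(f[2], f[3])
  expect_gt(f[3], 0.9)
})

test_that("IAAFT surrogates keep the amplitude distribution and spectrum", {
  set.seed(30)
  x <- logistic_series(250)
  y <- iaaft_surrogate(x)
  expect_equal(sort(y), sort(x), tolerance = 1e-12)
  sx <- Mod(fft(x)); sy <- Mod(fft(y))
  expect_lt(sqrt(mean((sx - sy)^2)) / sqrt(mean(sx^2)), 0.05)
  ph <- phase_surrogate(x)
  expect_equal(Mod(fft(ph)), Mod(fft(x)), tolerance = 1e-9)
  expect_equal(mean(ph), mean(x), tolerance = 1e-12)
})

test_that("dataset readers round-trip the supported dialects", {
  # generic CSV with header
  rec <- generate_recording(default_activity_specs(duration = 2), fs = 20,
                            seed = 14)
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p, "generic_csv", fs = 20)
  expect_equal(back$x, rec$x, tolerance = 1e-6)
  expect_equal(as.character(back$label), as.character(rec$label))

  # WISDM-style fixture with one malformed line
  wp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("33,Jogging,49105962326000,-0.69,12.68,0.50;",
               "33,Jogging,49106062271000,5.01,11.26,0.95;",
               "33,Jogging,49106112167000,bad,,;",
               "33,Walking,49106222305000,4.90,10.88,-0.08;"), wp)
  expect_warning(wrec <- read_recording(wp, "wisdm", fs = 20),
                 "1 malformed")
  expect_length(wrec, 3L)
  expect_equal(as.character(wrec$label), c("Jogging", "Jogging", "Walking"))
  expect_equal(wrec$x[2], 5.01)

  # PAMAP2-style fixture: 54 space-separated columns, hand accel at 5-7
  pp <- withr::local_tempfile(fileext = ".dat")
  row <- function(t, act, ax) paste(c(t, act, 100, 30, ax, 9.6, 1.2,
                                      rep(0, 47)), collapse = " ")
  writeLines(c(row(0.00, 1, 2.1), row(0.01, 1, 2.2), row(0.02, 2, 2.3)), pp)
  prec <- read_recording(pp, "pamap2", fs = 100)
  expect_length(prec, 3L)
  expect_equal(prec$x, c(2.1, 2.2, 2.3))
  expect_equal(as.character(prec$label),
               c("activity_1", "activity_1", "activity_2"))

  expect_error(read_recording("no_such_file.csv", "generic_csv"), "not found")
})
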