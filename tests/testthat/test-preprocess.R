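# Preprocessing: dF/F, event detection, high-pass, z-score/rectify, binning.

test_that("dF/F matches its definition and a brute-force oracle", {
  # constant trace: F == F0 everywhere
  f <- fluor_matrix(matrix(5, 10, 2), 20)
  expect_true(all(compute_dff(f) == 0))
  # two-frame trace: arithmetic forced by the formula
  f2 <- fluor_matrix(matrix(c(8, 12), 2, 1), 20)
  expect_equal(unclass(compute_dff(f2))[, 1], c(-0.2, 0.2))
  # random matrix vs independent two-line oracle
  set.seed(31)
  m <- matrix(runif(500, 1, 3), 100, 5)
  expect_equal(plain(compute_dff(fluor_matrix(m, 20))), brute_dff(m))
  # zero-F0 neuron is a named error
  bad <- fluor_matrix(cbind(a = c(-1, 1), b = c(1, 2)), 20)
  expect_error(compute_dff(bad), "F0 is zero.*a")
})

test_that("dF/F is invariant to positive rescaling of a neuron's raw trace", {
  set.seed(8)
  m <- matrix(runif(200, 1, 2), 50, 4)
  d1 <- compute_dff(fluor_matrix(m, 20))
  m[, 2] <- m[, 2] * 37.5
  d2 <- compute_dff(fluor_matrix(m, 20))
  expect_equal(unclass(d1), unclass(d2), tolerance = 1e-12)
})

test_that("event detection counts planted transients and applies thresholds", {
  # 4 well-separated planted transients, noiseless
  gt <- generate_ensembles(4, 1, 2, seed = 3)
  p <- sim_params(n_neurons = 4, n_ensembles = 1, duration = 60,
                  event_rate = 0, noise_sd = 0, drift_amplitude = 0,
                  background_rate = 0, seed = 3)
  s <- generate_session(gt, p, event_times = list(c(100L, 400L, 700L, 1000L)))
  ev <- detect_events(compute_dff(s$traces))
  member <- gt$membership[1, ] > 0
  expect_true(all(ev$per_neuron[member] == 4L))
  expect_true(all(ev$per_neuron[!member] == 0L))

  # all-zero trace: no events, zero-variance message not error
  z <- trace_matrix(matrix(0, 100, 1), "dff", 20)
  expect_message(ev0 <- detect_events(z), "zero-variance")
  expect_equal(unname(ev0$per_neuron), 0L)

  # amplitude below the 0.01 a.u. absolute floor yields no events
  x <- rep(0, 2000); x[500:505] <- 0.005
  small <- trace_matrix(matrix(x + rnorm(2000, 0, 1e-5), ncol = 1), "dff", 20)
  expect_equal(unname(detect_events(small)$per_neuron), 0L)
})

test_that("event counts are monotone non-increasing in the SD multiplier", {
  gt <- generate_ensembles(6, 2, 3, 0.2, seed = 12)
  p <- sim_params(n_neurons = 6, n_ensembles = 2, duration = 120,
                  event_rate = 0.2, noise_sd = 0.05, seed = 12)
  dff <- compute_dff(generate_session(gt, p)$traces)
  prev <- NULL
  for (mult in c(1, 2, 3, 5, 8)) {
    cnt <- detect_events(dff, event_config(sd_multiplier = mult))$per_neuron
    if (!is.null(prev)) expect_true(all(cnt <= prev))
    prev <- cnt
  }
})

test_that("high-pass rejects DC exactly and shapes the spectrum as designed", {
  fr <- 20
  # constant input -> all zero (mean removal + filter)
  const <- trace_matrix(matrix(7, 4000, 2), "dff", fr)
  expect_lt(max(abs(highpass_filter(const))), 1e-6 * 7)
  # 0.001 Hz drift attenuated > 90 % (measured mid-signal, away from edges)
  tt <- seq(0, 600, by = 1 / fr)
  slow <- trace_matrix(matrix(sin(2 * pi * 0.001 * tt), ncol = 1), "dff", fr)
  out <- highpass_filter(slow)
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  expect_lt(max(abs(out[mid, 1])), 0.1)
  # 1 Hz passband content preserved within 5 %
  fast <- trace_matrix(matrix(sin(2 * pi * 1 * tt), ncol = 1), "dff", fr)
  outf <- highpass_filter(fast)
  expect_equal(max(abs(outf[mid, 1])), 1, tolerance = 0.05)
  # short sessions warn but still filter
  shrt <- trace_matrix(matrix(rnorm(200), ncol = 1), "dff", fr)
  expect_warning(highpass_filter(shrt), "time constants")
})

test_that("z-score/rectify matches the column-standardize-and-clip oracle", {
  sym <- trace_matrix(matrix(c(-1, 1, -1, 1), 4, 1), "highpassed", 20)
  expect_equal(unclass(zscore_rectify(sym))[, 1], c(0, 1, 0, 1))

  set.seed(77)
  m <- matrix(rnorm(600), 100, 6)
  got <- zscore_rectify(trace_matrix(m, "highpassed", 20))
  expect_equal(plain(got), brute_zscore_rectify(m))
  expect_true(all(got >= 0))

  flat <- trace_matrix(cbind(rnorm(50), 0), "highpassed", 20)
  expect_message(z <- zscore_rectify(flat), "zero-SD")
  expect_true(all(unclass(z)[, 2] == 0))
})

test_that("binning averages frames, drops the partial tail and sets duration", {
  tm <- trace_matrix(matrix(abs(rnorm(9 * 3)), 9, 3), "zscored_rectified", 20)
  b <- bin_traces(tm, 4)
  expect_equal(nrow(b), 2L)                       # frame 9 dropped
  expect_equal(attr(b, "bin_duration"), 0.200)    # 4 frames at 20 Hz
  expect_equal(unclass(b)[1, ], colMeans(unclass(tm)[1:4, ]))
  # constant input: every bin equals the constant
  cm <- trace_matrix(matrix(2.5, 16, 2), "zscored_rectified", 20)
  expect_true(all(bin_traces(cm, 4) == 2.5))
  # sum aggregation is the mean scaled by bin_frames
  expect_equal(unclass(bin_traces(tm, 4, agg = "sum")),
               unclass(bin_traces(tm, 4)) * 4)
  expect_error(bin_traces(trace_matrix(matrix(1, 3, 1), "zscored_rectified", 20), 4),
               "cannot bin")
})

test_that("shapes are conserved through the stage chain and stages are enforced", {
  gt <- generate_ensembles(10, 2, 4, 0.2, seed = 21)
  p <- sim_params(n_neurons = 10, n_ensembles = 2, duration = 60, seed = 21)
  raw <- generate_session(gt, p)$traces
  dff <- compute_dff(raw)
  hp <- suppressWarnings(highpass_filter(dff))
  zr <- zscore_rectify(hp)
  expect_equal(dim(dff), dim(raw))
  expect_equal(dim(hp), dim(raw))
  expect_equal(dim(zr), dim(raw))
  expect_equal(nrow(bin_traces(zr, 4)), nrow(raw) %/% 4L)
  # stage contract: operations refuse inputs from the wrong stage
  expect_error(zscore_rectify(dff), "highpassed")
  expect_error(bin_traces(hp), "zscored_rectified")
  expect_error(detect_events(hp), "dff")
})
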