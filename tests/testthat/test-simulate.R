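# Synthetic-data generator: planted structure, kinetics, determinism.

test_that("disjoint ensemble supports give zero pairwise cosine", {
  gt <- generate_ensembles(30, 3, 6, max_overlap = 0, seed = 1)
  expect_equal(dim(gt$membership), c(3L, 30L))
  expect_true(all(gt$membership >= 0))
  expect_true(all(rowSums(gt$membership > 0) == 6))
  co <- cosine_similarity_matrix(gt$membership, gt$membership)
  expect_equal(max(co[upper.tri(co)]), 0)
  expect_equal(gt$pairwise_overlap, 0)
})

test_that("a single ensemble can span all neurons", {
  gt <- generate_ensembles(10, 1, 10, max_overlap = 0, seed = 7)
  expect_equal(sum(gt$membership[1, ] > 0), 10L)
  expect_equal(gt$pairwise_overlap, 0)
})

test_that("max_overlap cap is respected under rejection sampling", {
  gt <- generate_ensembles(50, 5, 8, max_overlap = 0.3, seed = 3)
  # verify by direct computation over all 10 pairs
  worst <- 0
  for (i in 1:4) for (j in (i + 1):5)
    worst <- max(worst, brute_cosine(gt$membership[i, ], gt$membership[j, ]))
  expect_lte(worst, 0.3)
  expect_equal(gt$pairwise_overlap, worst)
})

test_that("infeasible overlap constraints raise a named error", {
  expect_error(generate_ensembles(10, 3, 6, max_overlap = 0, seed = 1),
               "disjoint")
  expect_error(generate_ensembles(12, 6, 8, max_overlap = 0.05, seed = 1,
                                  max_tries = 50),
               "cosine")
})

test_that("a source-free session is identically its baseline", {
  gt <- generate_ensembles(8, 1, 4, seed = 2)
  p <- sim_params(n_neurons = 8, n_ensembles = 1, duration = 10,
                  event_rate = 0, noise_sd = 0, drift_amplitude = 0,
                  background_rate = 0, baseline = 1.5, seed = 2)
  s <- generate_session(gt, p)
  expect_true(all(s$traces == 1.5))
  expect_equal(lengths(s$occurrence_times), c(E1 = 0L))
})

test_that("a planted transient peaks after the rise and decays by 1/e over tau", {
  gt <- generate_ensembles(6, 1, 3, seed = 5)
  p <- sim_params(n_neurons = 6, n_ensembles = 1, duration = 30,
                  event_rate = 0, noise_sd = 0, drift_amplitude = 0,
                  background_rate = 0, amp_jitter_sigma = 0,
                  rise_frames = 2, decay_tau = 0.5, seed = 5)
  s <- generate_session(gt, p, event_times = list(100L))
  member <- which(gt$membership[1, ] > 0)[1]
  tr <- s$traces[, member] - p$baseline
  peak <- which.max(tr)
  expect_lte(abs(peak - 100L), p$rise_frames)
  n_tau <- round(p$decay_tau * p$frame_rate)
  expect_equal(tr[peak + n_tau] / tr[peak], exp(-1), tolerance = 0.05)
})

test_that("noiseless signal is non-negative and activation counts are Poisson", {
  counts <- vapply(1:200, function(i) {
    gt <- generate_ensembles(4, 1, 2, seed = i)
    p <- sim_params(n_neurons = 4, n_ensembles = 1, duration = 300,
                    event_rate = 0.1, noise_sd = 0, background_rate = 0,
                    seed = i)
    s <- generate_session(gt, p)
    expect_true(all(s$traces >= 0))
    length(s$occurrence_times[[1]])
  }, numeric(1))
  # mean activation count within 3 standard errors of event_rate * duration
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 200))
})

test_that("identical seeds reproduce sessions bit-for-bit", {
  p <- sim_params(n_neurons = 12, n_ensembles = 2, duration = 20,
                  neurons_per_ensemble = 4, seed = 42)
  gt <- generate_ensembles(12, 2, 4, 0.2, seed = 42)
  s1 <- generate_session(gt, p)
  s2 <- generate_session(gt, p)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$occurrence_times, s2$occurrence_times)
  # and the global RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_session(gt, p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("session pairs share exactly the planted fraction of ensembles", {
  p <- sim_params(n_neurons = 80, n_ensembles = 10, duration = 10,
                  neurons_per_ensemble = 4, max_overlap = 0, seed = 9,
                  background_rate = 0)
  pr <- generate_session_pair(p, shared_fraction = 0.5)
  expect_equal(nrow(pr$shared_map), 5L)
  ms <- brute_matching_score(pr$ensembles_a$membership,
                             pr$ensembles_b$membership)
  expect_equal(ms, 0.5)

  pr1 <- generate_session_pair(p, shared_fraction = 1)
  expect_equal(nrow(pr1$shared_map), 10L)
  expect_equal(brute_matching_score(pr1$ensembles_a$membership,
                                    pr1$ensembles_b$membership), 1)

  pr0 <- generate_session_pair(p, shared_fraction = 0)
  expect_equal(nrow(pr0$shared_map), 0L)
  expect_equal(brute_matching_score(pr0$ensembles_a$membership,
                                    pr0$ensembles_b$membership), 0)
})

test_that("the session triplet plants the requested reactivation design", {
  p <- sim_params(n_neurons = 40, n_ensembles = 6, duration = 10,
                  neurons_per_ensemble = 4, max_overlap = 0,
                  background_rate = 0, seed = 4)
  tri <- generate_session_triplet(p, rest_idx = 1:3, day2_idx = 1:2)
  expect_equal(tri$rest_map, 1:3)
  expect_equal(nrow(tri$ensembles$rest$membership), 3L)
  expect_equal(nrow(tri$ensembles$day2$membership), 2L)
  # rest patterns are copies of day1 patterns 1..3
  expect_equal(unname(tri$ensembles$rest$membership),
               unname(tri$ensembles$day1$membership[1:3, ]))
})
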