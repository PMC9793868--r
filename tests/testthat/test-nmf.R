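# NMF factorization and AICc rank selection.

test_that("exact low-rank matrices are reconstructed almost perfectly", {
  set.seed(5)
  for (r in c(1L, 3L, 5L)) {
    w <- matrix(runif(60 * r), 60, r)
    h <- matrix(runif(r * 12), r, 12)
    x <- binned_matrix(w %*% h, 4, 20)
    es <- nmf_factorize(x, r, factor_config(n_restarts = 10, seed = r,
                                            max_iter = 5000, rel_tol = 1e-10))
    rel_err <- sqrt(es$cost) / sqrt(sum(unclass(x)^2))
    expect_lt(rel_err, 1e-3)
  }
})

test_that("per-iteration cost is non-increasing in every logged run", {
  set.seed(6)
  x <- binned_matrix(matrix(runif(400), 40, 10), 4, 20)
  for (r in c(2L, 4L)) {
    es <- nmf_factorize(x, r, factor_config(n_restarts = 5, seed = r))
    expect_true(all(diff(es$cost_trace) <= 1e-8 * es$cost_trace[1]))
  }
})

test_that("factors are non-negative and pattern rows unit-norm; reconstruction
           is unchanged by the normalization", {
  set.seed(7)
  x <- binned_matrix(matrix(runif(300), 30, 10), 4, 20)
  es <- nmf_factorize(x, 3, factor_config(n_restarts = 5, seed = 1))
  expect_true(all(es$patterns >= 0))
  expect_true(all(es$occurrences >= 0))
  expect_equal(unname(sqrt(rowSums(es$patterns^2))), rep(1, 3))
  # residual identical to the unnormalized factorization's final cost
  recon <- es$occurrences %*% es$patterns
  expect_equal(sum((unclass(x) - recon)^2), es$cost, tolerance = 1e-10)
})

test_that("best-of-N-restarts cost is non-increasing in N", {
  set.seed(9)
  x <- binned_matrix(matrix(runif(600), 60, 10), 4, 20)
  costs <- vapply(c(1L, 10L, 50L), function(n)
    nmf_factorize(x, 3, factor_config(n_restarts = n, seed = 11))$cost,
    numeric(1))
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("degenerate inputs are rejected with informative errors", {
  z <- binned_matrix(matrix(0, 10, 4), 4, 20, session_id = "empty_sess")
  expect_error(nmf_factorize(z, 2), "empty_sess")
  x <- binned_matrix(matrix(runif(40), 10, 4), 4, 20)
  expect_error(nmf_factorize(x, 0), "rank")
  expect_error(nmf_factorize(x, 9), "rank")
})

test_that("AICc ties break toward the smaller rank", {
  expect_equal(caensembles:::choose_rank(2:5, c(3, 1, 1, 2)), 3L)
  expect_equal(caensembles:::choose_rank(1:3, c(7, 7, 7)), 1L)
})

test_that("AICc rejects overfit ranks on planted single-ensemble data", {
  gt <- generate_ensembles(12, 1, 12, seed = 31)
  p <- sim_params(n_neurons = 12, n_ensembles = 1, duration = 120,
                  event_rate = 0.2, noise_sd = 0.02, drift_amplitude = 0,
                  background_rate = 0, neurons_per_ensemble = 12, seed = 31)
  b <- quiet_preprocess(generate_session(gt, p)$traces)
  sel <- select_rank_aicc(b, factor_config(n_restarts = 10,
                                           rank_range = c(1, 4), seed = 2))
  expect_equal(sel$chosen_rank, 1L)
  expect_equal(sel$table$rank[which.min(sel$table$aicc)], sel$chosen_rank)
})

test_that("ranks too large for the AICc correction are excluded, not scored", {
  x <- binned_matrix(matrix(runif(60), 6, 10), 4, 20)
  # n = 60 observations, k = r * 16: r >= 4 makes n - k - 1 <= 0
  expect_message(
    sel <- select_rank_aicc(x, factor_config(n_restarts = 2,
                                             rank_range = c(1, 6), seed = 1)),
    "excluded")
  expect_true(all(sel$table$rank <= 3))
})

test_that("extraction is deterministic under a fixed seed", {
  s <- rank_recovery_session(404)
  b <- quiet_preprocess(s$session$traces)
  cfg <- factor_config(n_restarts = 5, rank_range = c(2, 4), seed = 99)
  e1 <- extract_ensembles(b, cfg)
  e2 <- extract_ensembles(b, cfg)
  expect_identical(e1$ensembles$patterns, e2$ensembles$patterns)
  expect_identical(e1$ensembles$occurrences, e2$ensembles$occurrences)
  expect_identical(e1$rank_table$table, e2$rank_table$table)
})

test_that("planted ensembles are recovered through the full extraction", {
  # noiseless planted rank-3 session: recovered patterns match planted ones
  s <- rank_recovery_session(515)
  b <- quiet_preprocess(s$session$traces)
  es <- nmf_factorize(b, 3, factor_config(n_restarts = 20, seed = 3))
  co <- cosine_similarity_matrix(s$gt$membership, es$patterns)
  expect_true(all(apply(unclass(co), 1, max) > 0.95))
})

test_that("patterns survive realistic clutter even when extra components appear", {
  # overlapping memberships + background transients: the chosen rank may
  # exceed the planted count (clutter is real structure), but every planted
  # pattern must still be recovered
  gt <- generate_ensembles(24, 3, 8, max_overlap = 0.25, seed = 61)
  p <- sim_params(n_neurons = 24, n_ensembles = 3, duration = 180,
                  noise_sd = 0.1, neurons_per_ensemble = 8,
                  max_overlap = 0.25, seed = 61)
  b <- quiet_preprocess(generate_session(gt, p)$traces)
  ext <- extract_ensembles(b, factor_config(n_restarts = 20,
                                            rank_range = c(1, 6), seed = 6))
  expect_gte(ext$rank_table$chosen_rank, 3L)
  co <- cosine_similarity_matrix(gt$membership, ext$ensembles$patterns)
  expect_gte(mean(apply(unclass(co), 1, max)), 0.9)
})
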