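# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are written against the definitions, not against the
# package implementation.

# Brute-force matching score: explicit double loop over every pattern pair.
brute_matching_score <- function(px, py, c_thresh = 0.6) {
  matched <- logical(nrow(px))
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(nrow(py))) {
      ni <- sqrt(sum(px[i, ]^2)); nj <- sqrt(sum(py[j, ]^2))
      cs <- if (ni == 0 || nj == 0) 0 else sum(px[i, ] * py[j, ]) / (ni * nj)
      if (cs > c_thresh) { matched[i] <- TRUE; break }
    }
  }
  mean(matched)
}

# Brute-force cosine between two vectors.
brute_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
}

# Two-line dF/F oracle: subtract column mean, divide by it.
brute_dff <- function(m) sweep(sweep(m, 2, colMeans(m)), 2, colMeans(m), "/")

# Column-standardize (population SD) then clip negatives.
brute_zscore_rectify <- function(m) {
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  z <- sweep(sweep(m, 2, mu), 2, sd_pop, "/")
  z[z < 0] <- 0
  z
}

# Strip class and metadata attributes, keeping only the numeric matrix.
plain <- function(x) {
  x <- unclass(x)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

# Random non-negative ensemble-set pair on a shared neuron space.
random_pattern_pair <- function(max_patterns = 8, max_neurons = 20) {
  nn <- sample(3:max_neurons, 1)
  nx <- sample(1:max_patterns, 1)
  ny <- sample(1:max_patterns, 1)
  # mix of sparse and dense rows so both matched and unmatched pairs occur
  mk <- function(k) {
    m <- matrix(runif(k * nn) * rbinom(k * nn, 1, 0.5), k, nn)
    m[rowSums(m) == 0, 1] <- 1  # avoid all-zero patterns
    m
  }
  list(x = mk(nx), y = mk(ny))
}

# Session generation at the frozen rank-recovery study conditions:
# 3 disjoint 6-neuron ensembles over 18 neurons, no background clutter.
rank_recovery_session <- function(seed) {
  gt <- generate_ensembles(18, 3, 6, max_overlap = 0, seed = seed)
  p <- sim_params(n_neurons = 18, n_ensembles = 3, duration = 180,
                  event_rate = 0.2, noise_sd = 0.05,
                  neurons_per_ensemble = 6, max_overlap = 0,
                  background_rate = 0, seed = seed)
  list(gt = gt, session = generate_session(gt, p))
}

# Session-pair parameters for the shared-fraction recovery study:
# 10 disjoint 4-neuron ensembles over 60 neurons.
shared_fraction_params <- function(seed, shared = 0.5) {
  sim_params(n_neurons = 60, n_ensembles = 10, duration = 180,
             event_rate = 0.2, noise_sd = 0.05, neurons_per_ensemble = 4,
             max_overlap = 0, background_rate = 0,
             shared_fraction = shared, seed = seed)
}

quiet_preprocess <- function(raw, ...) suppressWarnings(preprocess_session(raw, ...))
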