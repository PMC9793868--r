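# Synthetic-data generator: sessions of calcium traces with planted ensembles,
# controllable cross-session sharing, transient kinetics, drift and noise,
# plus ground truth for recovery scoring.

#' Simulation parameters
#'
#' Bundles and validates every knob of the synthetic session generator.
#' Defaults emulate miniscope recordings of a genetically encoded calcium
#' indicator in hippocampal CA1: 20 frames/s acquisition, transients with a
#' fast linear rise (2 frames) and exponential decay (tau = 0.5 s), a slowly
#' drifting baseline (< 0.005 Hz) and additive Gaussian noise.
#'
#' @param n_neurons number of neurons imaged.
#' @param n_ensembles number of co-active neuron subsets planted.
#' @param frame_rate acquisition rate, Hz.
#' @param duration session length, seconds.
#' @param event_rate ensemble activation rate, activations/s per ensemble.
#' @param decay_tau calcium-transient decay time constant, seconds.
#' @param rise_frames transient rise time, frames.
#' @param amplitude transient peak scale, arbitrary fluorescence units. The
#'   trace scale is arbitrary (indicator brightness varies), so it is exposed
#'   rather than fixed.
#' @param amp_jitter_sigma lognormal sigma of the multiplicative
#'   per-activation amplitude jitter.
#' @param baseline constant baseline fluorescence, a.u.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift, a.u.
#' @param drift_freq drift frequency, Hz; must be < 0.005 so the drift lies
#'   well below the 0.01 Hz high-pass cutoff it is meant to exercise.
#' @param background_rate per-neuron rate of independent (non-ensemble)
#'   transients, events/s; clutter for the factorization.
#' @param neurons_per_ensemble neurons per planted ensemble.
#' @param max_overlap maximum allowed pairwise cosine between planted
#'   membership patterns.
#' @param shared_fraction fraction of ensembles shared between a session pair.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_neurons = 40, n_ensembles = 5, frame_rate = 20,
                       duration = 180, event_rate = 0.1, decay_tau = 0.5,
                       rise_frames = 2, amplitude = 1, amp_jitter_sigma = 0.2,
                       baseline = 1, noise_sd = 0.05, drift_amplitude = 0.1,
                       drift_freq = 0.002, background_rate = 0.02,
                       neurons_per_ensemble = 8, max_overlap = 0.25,
                       shared_fraction = 0.5, seed = 1) {
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(decay_tau, "decay_tau", positive = TRUE)
  for (nm in c("event_rate", "amplitude", "amp_jitter_sigma", "baseline",
               "noise_sd", "drift_amplitude", "background_rate"))
    assert_scalar_num(get(nm), nm)
  if (event_rate < 0 || noise_sd < 0 || background_rate < 0)
    stop("rates and noise_sd must be >= 0", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  if (drift_freq >= 0.005)
    stop("drift_freq must be < 0.005 Hz (slow baseline drift)", call. = FALSE)
  if (drift_amplitude > baseline)
    warning("drift_amplitude exceeds baseline; noiseless traces may go negative")
  p <- list(n_neurons = as.integer(n_neurons),
            n_ensembles = as.integer(n_ensembles),
            frame_rate = frame_rate, duration = duration,
            event_rate = event_rate, decay_tau = decay_tau,
            rise_frames = as.integer(rise_frames), amplitude = amplitude,
            amp_jitter_sigma = amp_jitter_sigma, baseline = baseline,
            noise_sd = noise_sd, drift_amplitude = drift_amplitude,
            drift_freq = drift_freq, background_rate = background_rate,
            neurons_per_ensemble = as.integer(neurons_per_ensemble),
            max_overlap = max_overlap, shared_fraction = shared_fraction,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' Generate ground-truth ensemble membership patterns
#'
#' Plants `n_ensembles` non-negative membership patterns over `n_neurons`
#' neurons, each supported on `neurons_per_ensemble` neurons with weights
#' drawn uniformly from \[0.5, 1\], subject to a cap on the pairwise cosine
#' between any two patterns. With `max_overlap = 0` supports are sampled
#' disjointly; otherwise candidate patterns are rejection-sampled until the
#' cap holds against all previously accepted patterns.
#'
#' @param n_neurons,n_ensembles,neurons_per_ensemble pattern geometry.
#' @param max_overlap maximum allowed pairwise cosine, in \[0, 1).
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per ensemble before declaring
#'   the constraint infeasible.
#' @return a `ground_truth_ensembles` list: `membership`
#'   (n_ensembles x n_neurons), `neuron_ids`, and `pairwise_overlap` (the
#'   realized maximum pairwise cosine).
#' @examples
#' gt <- generate_ensembles(30, 3, 6, max_overlap = 0, seed = 1)
#' gt$pairwise_overlap  # 0: disjoint supports
#' @export
generate_ensembles <- function(n_neurons, n_ensembles, neurons_per_ensemble,
                               max_overlap = 0, seed = NULL,
                               max_tries = 5000L) {
  n_neurons <- as.integer(n_neurons)
  n_ensembles <- as.integer(n_ensembles)
  neurons_per_ensemble <- as.integer(neurons_per_ensemble)
  if (neurons_per_ensemble < 2L)
    stop("each ensemble needs >= 2 member neurons", call. = FALSE)
  if (max_overlap < 0 || max_overlap >= 1)
    stop("max_overlap must lie in [0, 1)", call. = FALSE)
  if (neurons_per_ensemble > n_neurons)
    stop("infeasible: neurons_per_ensemble exceeds n_neurons", call. = FALSE)
  if (max_overlap == 0 && n_ensembles * neurons_per_ensemble > n_neurons)
    stop(sprintf(paste("infeasible: max_overlap = 0 requires disjoint supports,",
                       "but %d ensembles x %d neurons > %d available"),
                 n_ensembles, neurons_per_ensemble, n_neurons), call. = FALSE)
  with_seed(seed, {
    membership <- matrix(0, n_ensembles, n_neurons)
    used <- integer(0)
    for (e in seq_len(n_ensembles)) {
      if (max_overlap == 0) {
        pool <- setdiff(seq_len(n_neurons), used)
        support <- sample(pool, neurons_per_ensemble)
        membership[e, support] <- runif(neurons_per_ensemble, 0.5, 1)
        used <- c(used, support)
        next
      }
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        support <- sample(n_neurons, neurons_per_ensemble)
        w <- numeric(n_neurons)
        w[support] <- runif(neurons_per_ensemble, 0.5, 1)
        if (e == 1L ||
            max(row_cosine(matrix(w, 1L), membership[seq_len(e - 1L), , drop = FALSE])) <= max_overlap) {
          membership[e, ] <- w
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste("infeasible: could not place ensemble %d with pairwise",
                           "cosine <= %.3g after %d attempts"),
                     e, max_overlap, max_tries), call. = FALSE)
    }
    rownames(membership) <- paste0("E", seq_len(n_ensembles))
    colnames(membership) <- paste0("n", seq_len(n_neurons))
    co <- row_cosine(membership, membership)
    pairwise <- if (n_ensembles > 1L) max(co[upper.tri(co)]) else 0
    structure(list(membership = membership,
                   neuron_ids = seq_len(n_neurons),
                   pairwise_overlap = pairwise),
              class = "ground_truth_ensembles")
  })
}

# Calcium transient kernel: linear rise over rise_frames to peak 1, then
# exponential decay with time constant decay_tau (seconds). Truncated at 8 tau.
calcium_kernel <- function(rise_frames, decay_tau, frame_rate) {
  n_decay <- max(1L, ceiling(8 * decay_tau * frame_rate))
  c(seq_len(rise_frames) / rise_frames,
    exp(-(seq_len(n_decay)) / (decay_tau * frame_rate)))
}

# Add `kernel * amp * weights` to `traces` starting at frame t0 (truncating at
# the session end). traces is modified and returned.
add_transient <- function(traces, t0, kernel, amp, weights) {
  n_frames <- nrow(traces)
  len <- min(length(kernel), n_frames - t0 + 1L)
  if (len < 1L) return(traces)
  idx <- t0:(t0 + len - 1L)
  nz <- which(weights > 0)
  traces[idx, nz] <- traces[idx, nz] +
    outer(kernel[seq_len(len)] * amp, weights[nz])
  traces
}

#' Simulate one session of calcium traces from planted ensembles
#'
#' The trace of each neuron is a constant baseline, plus a slow sinusoidal
#' drift, plus the membership-weighted calcium transient of every activation
#' of every ensemble it belongs to, plus independent background transients,
#' plus additive Gaussian noise. Ensemble activation counts are
#' Poisson(`event_rate * duration`) with activation times uniform over the
#' session, unless fixed times are supplied via `event_times`.
#'
#' @param gt `ground_truth_ensembles` from [generate_ensembles()].
#' @param params `sim_params`.
#' @param session_id session label.
#' @param event_times optional list (one sorted integer vector of activation
#'   frames per ensemble) overriding the Poisson draw — used to plant exactly
#'   known activations.
#' @return a `ground_truth_session` list: `traces` (a [fluor_matrix()]),
#'   `occurrence_times` (per-ensemble activation frames), `params`.
#' @export
generate_session <- function(gt, params, session_id = "session",
                             event_times = NULL) {
  stopifnot(inherits(gt, "ground_truth_ensembles"), inherits(params, "sim_params"))
  if (ncol(gt$membership) != params$n_neurons)
    stop("ground truth and params disagree on n_neurons", call. = FALSE)
  n_frames <- floor(params$duration * params$frame_rate)
  n_ens <- nrow(gt$membership)
  kernel <- calcium_kernel(params$rise_frames, params$decay_tau, params$frame_rate)
  with_seed(params$seed, {
    traces <- matrix(params$baseline, n_frames, params$n_neurons)
    # slow drift: common frequency, random phase per neuron
    if (params$drift_amplitude > 0) {
      tt <- (seq_len(n_frames) - 1L) / params$frame_rate
      phase <- runif(params$n_neurons, 0, 2 * pi)
      traces <- traces + params$drift_amplitude *
        sin(outer(2 * pi * params$drift_freq * tt, rep(1, params$n_neurons)) +
              matrix(phase, n_frames, params$n_neurons, byrow = TRUE))
    }
    occurrence_times <- vector("list", n_ens)
    names(occurrence_times) <- rownames(gt$membership)
    for (e in seq_len(n_ens)) {
      times <- if (!is.null(event_times)) as.integer(event_times[[e]])
      else {
        k <- rpois(1L, params$event_rate * params$duration)
        if (k > 0) sort(sample.int(n_frames, k, replace = TRUE)) else integer(0)
      }
      occurrence_times[[e]] <- times
      for (t0 in times) {
        amp <- params$amplitude * rlnorm(1L, 0, params$amp_jitter_sigma)
        traces <- add_transient(traces, t0, kernel, amp, gt$membership[e, ])
      }
    }
    # independent per-neuron background transients (clutter)
    if (params$background_rate > 0) {
      for (i in seq_len(params$n_neurons)) {
        k <- rpois(1L, params$background_rate * params$duration)
        if (k == 0) next
        for (t0 in sort(sample.int(n_frames, k, replace = TRUE))) {
          amp <- 0.5 * params$amplitude * rlnorm(1L, 0, params$amp_jitter_sigma)
          w <- numeric(params$n_neurons); w[i] <- 1
          traces <- add_transient(traces, t0, kernel, amp, w)
        }
      }
    }
    if (params$noise_sd > 0)
      traces <- traces + matrix(rnorm(length(traces), 0, params$noise_sd),
                                n_frames, params$n_neurons)
    structure(list(traces = fluor_matrix(traces, params$frame_rate, session_id,
                                         neuron_ids = colnames(gt$membership)),
                   occurrence_times = occurrence_times,
                   params = params),
              class = "ground_truth_session")
  })
}

#' Simulate a pair of sessions sharing a controllable fraction of ensembles
#'
#' Emulates a Day 1 / Day 2 context design: session B re-uses
#' `round(shared_fraction * n_ensembles)` of session A's planted patterns and
#' replaces the rest with fresh patterns whose pairwise cosine against every
#' session-A pattern (and each other) stays below `params$max_overlap`, so
#' the ideal matching score of A against B equals
#' `round(shared_fraction * n) / n`.
#'
#' @param params `sim_params`; `shared_fraction` and `seed` may be overridden
#'   by the dedicated arguments.
#' @param shared_fraction fraction of A's ensembles copied into B.
#' @param seed integer seed for the whole pair.
#' @return list with `session_a`, `session_b` (each a
#'   `ground_truth_session`), `ensembles_a`, `ensembles_b`, and `shared_map`
#'   (data.frame of copied indices `a` -> `b`).
#' @export
generate_session_pair <- function(params,
                                  shared_fraction = params$shared_fraction,
                                  seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  n_ens <- params$n_ensembles
  n_shared <- as.integer(round(shared_fraction * n_ens))
  n_fresh <- n_ens - n_shared
  # one low-overlap pool guarantees fresh B patterns stay dissimilar to all of A
  pool <- generate_ensembles(params$n_neurons, n_ens + n_fresh,
                             params$neurons_per_ensemble, params$max_overlap,
                             seed = derive_seed(seed, "ensembles"))
  memb_a <- pool$membership[seq_len(n_ens), , drop = FALSE]
  shared_idx <- if (n_shared > 0) sort(with_seed(derive_seed(seed, "shared"),
                                                 sample(n_ens, n_shared))) else integer(0)
  memb_b <- rbind(memb_a[shared_idx, , drop = FALSE],
                  pool$membership[seq_len(n_fresh) + n_ens, , drop = FALSE])
  if (nrow(memb_b) > 0) rownames(memb_b) <- paste0("E", seq_len(nrow(memb_b)))
  mk_gt <- function(m) {
    co <- row_cosine(m, m)
    structure(list(membership = m, neuron_ids = seq_len(ncol(m)),
                   pairwise_overlap = if (nrow(m) > 1) max(co[upper.tri(co)]) else 0),
              class = "ground_truth_ensembles")
  }
  gt_a <- mk_gt(memb_a)
  gt_b <- mk_gt(memb_b)
  pa <- params; pa$seed <- derive_seed(seed, "session_a")
  pb <- params; pb$seed <- derive_seed(seed, "session_b")
  list(session_a = generate_session(gt_a, pa, "day1_context"),
       session_b = generate_session(gt_b, pb, "day2_context"),
       ensembles_a = gt_a,
       ensembles_b = gt_b,
       shared_map = data.frame(a = shared_idx,
                               b = seq_len(n_shared)))
}

#' Simulate a Day 1 context / rest / Day 2 context session triplet
#'
#' Plants a three-session reactivation design: all `params$n_ensembles`
#' patterns are active in the Day 1 context session; the ensembles indexed by
#' `rest_idx` recur in the rest session and those indexed by `day2_idx` recur
#' in the Day 2 context session. Optional fresh (session-unique) patterns can
#' be added to the rest and Day 2 sessions.
#'
#' @param params `sim_params`.
#' @param rest_idx indices of Day 1 ensembles re-activated in rest.
#' @param day2_idx indices of Day 1 ensembles re-activated on Day 2.
#' @param n_fresh_rest,n_fresh_day2 counts of additional session-unique
#'   patterns.
#' @param seed integer seed.
#' @return list of the three `ground_truth_session`s (`day1`, `rest`, `day2`),
#'   the per-session ground-truth ensembles, and the planted index maps.
#' @export
generate_session_triplet <- function(params, rest_idx, day2_idx,
                                     n_fresh_rest = 0L, n_fresh_day2 = 0L,
                                     seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  n_ens <- params$n_ensembles
  rest_idx <- sort(as.integer(rest_idx)); day2_idx <- sort(as.integer(day2_idx))
  stopifnot(all(rest_idx >= 1 & rest_idx <= n_ens),
            all(day2_idx >= 1 & day2_idx <= n_ens))
  pool <- generate_ensembles(params$n_neurons,
                             n_ens + n_fresh_rest + n_fresh_day2,
                             params$neurons_per_ensemble, params$max_overlap,
                             seed = derive_seed(seed, "ensembles"))
  memb <- pool$membership
  mk_gt <- function(m) {
    rownames(m) <- paste0("E", seq_len(nrow(m)))
    co <- row_cosine(m, m)
    structure(list(membership = m, neuron_ids = seq_len(ncol(m)),
                   pairwise_overlap = if (nrow(m) > 1) max(co[upper.tri(co)]) else 0),
              class = "ground_truth_ensembles")
  }
  gt_day1 <- mk_gt(memb[seq_len(n_ens), , drop = FALSE])
  gt_rest <- mk_gt(memb[c(rest_idx, seq_len(n_fresh_rest) + n_ens), , drop = FALSE])
  gt_day2 <- mk_gt(memb[c(day2_idx, seq_len(n_fresh_day2) + n_ens + n_fresh_rest), ,
                        drop = FALSE])
  sess <- function(gt, label) {
    p <- params
    p$n_ensembles <- nrow(gt$membership)
    p$seed <- derive_seed(seed, label)
    generate_session(gt, p, label)
  }
  list(day1 = sess(gt_day1, "day1_context"),
       rest = sess(gt_rest, "day1_rest"),
       day2 = sess(gt_day2, "day2_context"),
       ensembles = list(day1 = gt_day1, rest = gt_rest, day2 = gt_day2),
       rest_map = rest_idx, day2_map = day2_idx)
}
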