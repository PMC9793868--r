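# End-to-end orchestration: simulate (or load) -> preprocess -> events ->
# extract -> match / reactivation, with a machine-readable JSON report.

#' Assemble a pipeline run configuration
#'
#' Either `trace_files` (named list of per-session trace paths, neuron
#' columns aligned across sessions) or `simulation` (a [sim_params()], in
#' which case a session pair — or triplet when `triplet` maps are given — is
#' generated) must be supplied. One run seed deterministically derives
#' per-stage seeds, so stages can be re-run in isolation.
#'
#' @param simulation optional [sim_params()] for synthetic input.
#' @param trace_files optional named character vector of trace-matrix paths.
#' @param trace_format `"csv"` or `"parquet"`.
#' @param triplet optional list with `rest_idx`, `day2_idx` (and optionally
#'   `n_fresh_rest`, `n_fresh_day2`) requesting the three-session
#'   reactivation design.
#' @param cutoff_hz,bin_frames preprocessing parameters.
#' @param event_cfg an [event_config()].
#' @param factor_cfg a [factor_config()].
#' @param match_cfg a [match_config()].
#' @param out_dir where to persist intermediate artifacts and the report.
#' @param seed run seed.
#' @param verbose emit per-stage log messages.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulation = NULL, trace_files = NULL,
                       trace_format = "csv", triplet = NULL,
                       cutoff_hz = 0.01, bin_frames = 4L,
                       event_cfg = event_config(),
                       factor_cfg = factor_config(),
                       match_cfg = match_config(),
                       out_dir = tempfile("caens_run_"), seed = 1L,
                       verbose = TRUE) {
  if (is.null(simulation) && is.null(trace_files))
    stop("either `simulation` params or `trace_files` must be given", call. = FALSE)
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_params"))
  if (!is.null(trace_files)) {
    missing <- trace_files[!file.exists(trace_files)]
    if (length(missing))
      stop(sprintf("trace file(s) not found: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    if (is.null(names(trace_files)) || any(names(trace_files) == ""))
      stop("trace_files must be a named vector (names = session labels)",
           call. = FALSE)
  }
  structure(list(simulation = simulation, trace_files = trace_files,
                 trace_format = trace_format, triplet = triplet,
                 cutoff_hz = cutoff_hz, bin_frames = as.integer(bin_frames),
                 event_cfg = event_cfg, factor_cfg = factor_cfg,
                 match_cfg = match_cfg, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Flat, human-editable mapping of the [run_config()] fields (nested
#' `event`, `factorization`, `match`, `simulation`, `triplet` blocks map to
#' the corresponding config constructors). Unknown keys are errors.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("simulation", "trace_files", "trace_format", "triplet",
             "cutoff_hz", "bin_frames", "event", "factorization", "match",
             "out_dir", "seed", "verbose")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  args <- list()
  if (!is.null(y$simulation)) args$simulation <- do.call(sim_params, y$simulation)
  if (!is.null(y$trace_files)) args$trace_files <- unlist(y$trace_files)
  if (!is.null(y$event)) args$event_cfg <- do.call(event_config, y$event)
  if (!is.null(y$factorization)) args$factor_cfg <- do.call(factor_config, y$factorization)
  if (!is.null(y$match)) args$match_cfg <- do.call(match_config, y$match)
  for (k in c("trace_format", "triplet", "cutoff_hz", "bin_frames", "out_dir",
              "seed", "verbose"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

log_stage <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(paste0("[caensembles] ", fmt), ...))
  invisible(NULL)
}

# `tenv` is an environment holding the named list `timings`, mutated in place.
run_stage <- function(cfg, stage, session_id, tenv, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for session '%s': %s",
                 stage, session_id, conditionMessage(e)), call. = FALSE))
  tenv$timings[[paste(stage, session_id, sep = ":")]] <-
    proc.time()[["elapsed"]] - t0
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> preprocess -> event detection -> ensemble
#' extraction per session, then cross-session matching (and, for a
#' three-session design, the reactivation analysis). Every intermediate
#' artifact is persisted under `cfg$out_dir`, and the run report — ensemble
#' counts, rank tables, matching scores, reactivation percentages, event
#' counts, version, config echo and per-stage wall-clock — is written as
#' `report.json`. Numeric report fields are reproduced exactly by re-running
#' with the same config (timing fields excluded; see [report_hash()]).
#'
#' @param cfg a [run_config()] or the path to a YAML config file.
#' @return the run report, invisibly (a `run_report` list).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tenv <- new.env(); tenv$timings <- list()

  # --- stage: acquire sessions ------------------------------------------
  ground_truth <- NULL
  if (!is.null(cfg$simulation)) {
    p <- cfg$simulation
    if (!is.null(cfg$triplet)) {
      sim <- run_stage(cfg, "simulate", "triplet", tenv,
        generate_session_triplet(p, cfg$triplet$rest_idx, cfg$triplet$day2_idx,
                                 cfg$triplet$n_fresh_rest %||% 0L,
                                 cfg$triplet$n_fresh_day2 %||% 0L,
                                 seed = derive_seed(cfg$seed, "simulate")))
      sessions <- list(day1_context = sim$day1$traces,
                       day1_rest = sim$rest$traces,
                       day2_context = sim$day2$traces)
      ground_truth <- sim
    } else {
      sim <- run_stage(cfg, "simulate", "pair", tenv,
        generate_session_pair(p, seed = derive_seed(cfg$seed, "simulate")))
      sessions <- list(day1_context = sim$session_a$traces,
                       day2_context = sim$session_b$traces)
      ground_truth <- sim
    }
    write_ground_truth(ground_truth, file.path(cfg$out_dir, "ground_truth.json"))
    for (nm in names(sessions))
      write_trace_matrix(sessions[[nm]],
                         file.path(cfg$out_dir, paste0(nm, "_raw.csv")))
    log_stage(cfg, "simulated %d session(s): %s", length(sessions),
              paste(names(sessions), collapse = ", "))
  } else {
    sessions <- lapply(names(cfg$trace_files), function(nm)
      run_stage(cfg, "load", nm, tenv,
                read_trace_matrix(cfg$trace_files[[nm]], cfg$trace_format)))
    names(sessions) <- names(cfg$trace_files)
    ids <- lapply(sessions, colnames)
    if (length(unique(ids)) != 1L)
      stop("sessions disagree on neuron ids; columns must be aligned",
           call. = FALSE)
    log_stage(cfg, "loaded %d session(s)", length(sessions))
  }

  # --- stages: preprocess, events, extract per session ------------------
  results <- list()
  for (nm in names(sessions)) {
    raw <- sessions[[nm]]
    log_stage(cfg, "%s: %d frames x %d neurons in", nm, nrow(raw), ncol(raw))
    dff <- run_stage(cfg, "preprocess", nm, tenv, compute_dff(raw))
    ev <- run_stage(cfg, "events", nm, tenv,
                    detect_events(dff, cfg$event_cfg))
    binned <- run_stage(cfg, "preprocess", nm, tenv,
      bin_traces(zscore_rectify(highpass_filter(dff, cfg$cutoff_hz)),
                 cfg$bin_frames))
    stopifnot(all(unclass(binned) >= 0))
    fcfg <- cfg$factor_cfg
    fcfg$seed <- derive_seed(cfg$seed, paste0("extract:", nm))
    ext <- run_stage(cfg, "extract", nm, tenv,
                     extract_ensembles(binned, fcfg))
    log_stage(cfg, "%s: %d bins x %d neurons -> %d ensembles", nm,
              nrow(binned), ncol(binned), ext$ensembles$n_ensembles)
    write_event_counts(ev, file.path(cfg$out_dir, paste0(nm, "_events.csv")))
    write_rank_table(ext$rank_table,
                     file.path(cfg$out_dir, paste0(nm, "_ranks.csv")))
    write_ensemble_set(ext$ensembles,
                       file.path(cfg$out_dir, paste0(nm, "_ensembles.json")),
                       config = fcfg)
    results[[nm]] <- list(events = ev, ensembles = ext$ensembles,
                          rank_table = ext$rank_table)
  }

  # --- stage: matching / reactivation -----------------------------------
  nms <- names(results)
  matches <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i == j) next
    key <- paste(nms[i], nms[j], sep = "->")
    mr <- run_stage(cfg, "match", key, tenv,
                    matching_score(results[[nms[i]]]$ensembles,
                                   results[[nms[j]]]$ensembles, cfg$match_cfg))
    write_match_result(mr, file.path(cfg$out_dir,
                                     paste0("match_", nms[i], "_vs_", nms[j])))
    plot_similarity_heatmap(mr, file.path(cfg$out_dir,
      paste0("match_", nms[i], "_vs_", nms[j], ".png")))
    matches[[key]] <- mr
    log_stage(cfg, "MS(%s, %s) = %.3f", nms[i], nms[j], mr$matching_score)
  }
  reactivation <- NULL
  if (all(c("day1_context", "day1_rest", "day2_context") %in% nms)) {
    reactivation <- run_stage(cfg, "reactivation", "triplet", tenv,
      reactivation_analysis(results$day1_context$ensembles,
                            results$day1_rest$ensembles,
                            results$day2_context$ensembles, cfg$match_cfg))
  }

  report <- structure(list(
    package_version = as.character(packageVersion("caensembles")),
    seed = cfg$seed,
    config = config_echo(cfg),
    sessions = lapply(results, function(r) list(
      n_ensembles = r$ensembles$n_ensembles,
      nmf_cost = r$ensembles$cost,
      rank_table = r$rank_table$table,
      chosen_rank = r$rank_table$chosen_rank,
      mean_events_per_neuron = r$events$per_session_mean,
      events_per_neuron = as.list(r$events$per_neuron))),
    matching_scores = lapply(matches, function(m) m$matching_score),
    reactivation = if (!is.null(reactivation)) unclass(reactivation),
    timings_s = tenv$timings), class = "run_report")
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       force = TRUE)
  log_stage(cfg, "report written to %s", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}

# Serializable echo of the exact resolved configuration.
config_echo <- function(cfg) {
  e <- unclass(cfg)
  e$simulation <- if (!is.null(e$simulation)) unclass(e$simulation)
  e$event_cfg <- unclass(e$event_cfg)
  e$factor_cfg <- unclass(e$factor_cfg)
  e$match_cfg <- unclass(e$match_cfg)
  e
}

#' Determinism hash of a run report
#'
#' Serializes the report without its timing fields and output directory and
#' hashes the result, so two runs with the same config and inputs can be
#' checked for exact numeric reproducibility.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return a character scalar (md5 of the canonical JSON).
#' @export
report_hash <- function(report) {
  r <- unclass(report)
  r$timings_s <- NULL
  r$config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(r, tmp, digits = NA, auto_unbox = TRUE, force = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}
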