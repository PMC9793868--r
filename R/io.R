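# Readers/writers. Trace matrices travel as delimited text (CSV with a small
# commented metadata header) or as a columnar binary container (Parquet via
# arrow, metadata carried in the file's R attributes). Ensemble sets, ground
# truth and run reports travel as JSON.

meta_header <- function(x, extra = character()) {
  c("# caensembles matrix",
    sprintf("# session_id: %s", attr(x, "session_id")),
    sprintf("# frame_rate: %s", format(attr(x, "frame_rate"), digits = 17)),
    extra)
}

parse_meta <- function(lines) {
  kv <- sub("^# *", "", lines[-1])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Write a trace or fluorescence matrix
#'
#' `format = "csv"`: plain delimited text — commented metadata lines, then a
#' header row of neuron ids, then one row per frame at full precision.
#' `format = "parquet"`: a single-file columnar binary container holding the
#' same columns with the metadata attached as file-level attributes
#' (requires the `arrow` package).
#'
#' @param x a [fluor_matrix()] or [trace_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_trace_matrix <- function(x, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "fluor_matrix") || inherits(x, "trace_matrix"))
  stage <- attr(x, "stage")
  kind <- if (inherits(x, "fluor_matrix")) "fluor" else "trace"
  if (format == "csv") {
    extra <- c(sprintf("# kind: %s", kind),
               if (!is.null(stage)) sprintf("# stage: %s", stage))
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(meta_header(x, extra), con)
    writeLines(paste(colnames(x), collapse = ","), con)
    m <- unclass(x)
    # %.17g round-trips doubles exactly
    body <- matrix(sprintf("%.17g", m), nrow(m))
    writeLines(apply(body, 1L, paste, collapse = ","), con)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet output", call. = FALSE)
    d <- as.data.frame(unclass(x))
    attr(d, "session_id") <- attr(x, "session_id")
    attr(d, "frame_rate") <- attr(x, "frame_rate")
    attr(d, "kind") <- kind
    attr(d, "stage") <- stage
    arrow::write_parquet(d, path)
  }
  invisible(path)
}

#' Read a trace or fluorescence matrix
#'
#' Counterpart of [write_trace_matrix()]; the round trip is lossless for
#' values, neuron ids and metadata. Malformed delimited files (ragged rows,
#' non-numeric cells) raise a parse error citing the offending data row.
#'
#' @param path input file.
#' @param format `"csv"` or `"parquet"`.
#' @return a [fluor_matrix()] or [trace_matrix()] according to the stored
#'   metadata.
#' @export
read_trace_matrix <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    head_lines <- readLines(path, n = 50L)
    n_meta <- sum(startsWith(head_lines, "#"))
    if (n_meta < 1L || head_lines[1] != "# caensembles matrix")
      stop(sprintf("%s: missing metadata header", path), call. = FALSE)
    meta <- parse_meta(head_lines[seq_len(n_meta)])
    if (is.null(meta$frame_rate))
      stop(sprintf("%s: metadata lacks frame_rate", path), call. = FALSE)
    dt <- data.table::fread(path, skip = n_meta, header = TRUE, sep = ",",
                            colClasses = "character", data.table = FALSE)
    vals <- suppressWarnings(
      vapply(dt, as.numeric, numeric(nrow(dt)), USE.NAMES = TRUE))
    if (nrow(dt) == 1L) vals <- matrix(vals, 1L)
    dimnames(vals) <- list(NULL, names(dt))
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("%s: non-numeric value at data row %d, column '%s'",
                   path, bad[["row"]], colnames(vals)[bad[["col"]]]),
           call. = FALSE)
    }
    kind <- meta$kind %||% "fluor"
    fr <- as.numeric(meta$frame_rate)
    sid <- meta$session_id %||% "session"
    if (kind == "trace")
      trace_matrix(vals, meta$stage, fr, sid)
    else
      fluor_matrix(vals, fr, sid)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for parquet input", call. = FALSE)
    d <- arrow::read_parquet(path)
    vals <- as.matrix(as.data.frame(d))
    dimnames(vals) <- list(NULL, colnames(vals))
    fr <- attr(d, "frame_rate")
    sid <- attr(d, "session_id") %||% "session"
    if (is.null(fr)) stop(sprintf("%s: metadata lacks frame_rate", path), call. = FALSE)
    if (identical(attr(d, "kind"), "trace"))
      trace_matrix(vals, attr(d, "stage"), fr, sid)
    else
      fluor_matrix(vals, fr, sid)
  }
}

#' Write an ensemble set as JSON
#'
#' Serializes patterns, occurrences, cost, session id and (optionally) the
#' factorization config for audit. [read_ensemble_set()] restores the object
#' losslessly at full double precision.
#'
#' @param es an [ensemble_set()].
#' @param path output `.json` file.
#' @param config optional [factor_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_ensemble_set <- function(es, path, config = NULL) {
  stopifnot(inherits(es, "ensemble_set"))
  obj <- list(session_id = es$session_id,
              n_ensembles = es$n_ensembles,
              neuron_ids = colnames(es$patterns),
              patterns = es$patterns,
              occurrences = es$occurrences,
              cost = es$cost,
              cost_trace = es$cost_trace,
              config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read an ensemble set written by [write_ensemble_set()]
#' @param path `.json` file.
#' @return an [ensemble_set()].
#' @export
read_ensemble_set <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ensemble file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  es <- ensemble_set(obj$patterns, obj$occurrences, obj$session_id,
                     cost = obj$cost, cost_trace = obj$cost_trace)
  colnames(es$patterns) <- obj$neuron_ids
  es
}

#' Write ground truth (memberships, occurrence times, maps, params) as JSON
#' @param gt list as returned by [generate_session_pair()] or
#'   [generate_session_triplet()], or a single `ground_truth_session`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(serialize_gt(gt), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

serialize_gt <- function(x) {
  if (inherits(x, "ground_truth_session"))
    return(list(occurrence_times = x$occurrence_times,
                params = unclass(x$params),
                session_id = attr(x$traces, "session_id")))
  if (inherits(x, "ground_truth_ensembles"))
    return(list(membership = x$membership, neuron_ids = x$neuron_ids,
                pairwise_overlap = x$pairwise_overlap))
  if (is.list(x)) return(lapply(x, serialize_gt))
  x
}

#' Write per-neuron event counts as delimited text
#' @param ev an `event_counts` object from [detect_events()].
#' @param path output `.csv` file (columns `neuron_id`, `n_events`).
#' @return `path`, invisibly.
#' @export
write_event_counts <- function(ev, path) {
  stopifnot(inherits(ev, "event_counts"))
  utils::write.csv(data.frame(neuron_id = names(ev$per_neuron),
                              n_events = as.integer(ev$per_neuron)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an AICc rank-selection table as delimited text
#' @param sel a `rank_selection` from [select_rank_aicc()].
#' @param path output `.csv` file.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(sel, path) {
  stopifnot(inherits(sel, "rank_selection"))
  tab <- sel$table
  tab$chosen <- tab$rank == sel$chosen_rank
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a match result (similarity matrix + JSON summary)
#'
#' The similarity matrix goes to `<path>.csv`; the summary (sessions,
#' threshold, matching score, per-ensemble best partners) to `<path>.json`.
#'
#' @param mr a `match_result` from [matching_score()].
#' @param path output path stem (extensions are appended).
#' @return the JSON path, invisibly.
#' @export
write_match_result <- function(mr, path) {
  stopifnot(inherits(mr, "match_result"))
  utils::write.csv(as.data.frame(unclass(mr$similarity)),
                   paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(session_x = attr(mr$similarity, "session_x"),
         session_y = attr(mr$similarity, "session_y"),
         threshold_c = mr$threshold_c,
         matching_score = mr$matching_score,
         matched_x = mr$matched_x,
         best_partner = mr$best_partner),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(paste0(path, ".json"))
}
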