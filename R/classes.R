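# S3 containers for the pipeline's domain objects. All are plain matrices or
# lists with attributes, so they serialize to delimited text / JSON losslessly.

#' Raw fluorescence matrix
#'
#' Container for a session's raw fluorescence traces F(t): one row per frame,
#' one column per neuron, with the acquisition frame rate attached. Columns
#' are named by stable neuron ids so that neuron identity can be validated
#' across sessions.
#'
#' @param values numeric matrix, frames x neurons, all finite.
#' @param frame_rate acquisition rate in Hz (> 0).
#' @param session_id character label for the session.
#' @param neuron_ids optional integer/character neuron labels; defaults to
#'   existing column names or `n1..nK`.
#' @return a `fluor_matrix` object (a matrix with metadata attributes).
#' @examples
#' f <- fluor_matrix(matrix(runif(40), 10, 4), frame_rate = 20)
#' dim(f)
#' @export
fluor_matrix <- function(values, frame_rate = 20, session_id = "session",
                         neuron_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("need at least one frame", call. = FALSE)
  if (!all(is.finite(values))) stop("fluorescence values must be finite", call. = FALSE)
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  if (is.null(neuron_ids)) {
    neuron_ids <- colnames(values)
    if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(ncol(values)))
  }
  if (length(neuron_ids) != ncol(values))
    stop("neuron_ids length must equal the number of neuron columns", call. = FALSE)
  colnames(values) <- as.character(neuron_ids)
  structure(values,
            frame_rate = frame_rate,
            session_id = as.character(session_id),
            class = c("fluor_matrix", "matrix", "array"))
}

#' Processed trace matrix
#'
#' A fluorescence-derived trace matrix at a named processing stage:
#' `"dff"` (\eqn{\Delta F/F}), `"highpassed"`, or `"zscored_rectified"`.
#' The rectified stage is non-negative by construction.
#'
#' @param values numeric matrix, frames x neurons.
#' @param stage one of `"dff"`, `"highpassed"`, `"zscored_rectified"`.
#' @param frame_rate Hz.
#' @param session_id session label.
#' @return a `trace_matrix` object.
#' @export
trace_matrix <- function(values, stage, frame_rate = 20, session_id = "session") {
  stage <- match.arg(stage, c("dff", "highpassed", "zscored_rectified"))
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  if (stage == "zscored_rectified" && any(values < 0))
    stop("zscored_rectified traces must be non-negative", call. = FALSE)
  assert_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("n", seq_len(ncol(values)))
  structure(values,
            stage = stage,
            frame_rate = frame_rate,
            session_id = as.character(session_id),
            class = c("trace_matrix", "matrix", "array"))
}

trace_stage <- function(x) attr(x, "stage")

#' Temporally binned activity matrix
#'
#' @param values numeric non-negative matrix, bins x neurons.
#' @param bin_frames number of frames aggregated per bin.
#' @param frame_rate original acquisition rate in Hz.
#' @param session_id session label.
#' @return a `binned_matrix` with `bin_duration = bin_frames / frame_rate`
#'   seconds attached.
#' @export
binned_matrix <- function(values, bin_frames, frame_rate = 20,
                          session_id = "session") {
  values <- as.matrix(values)
  if (any(values < 0)) stop("binned activity must be non-negative", call. = FALSE)
  bin_frames <- as.integer(bin_frames)
  if (bin_frames < 1L) stop("bin_frames must be >= 1", call. = FALSE)
  structure(values,
            bin_frames = bin_frames,
            bin_duration = bin_frames / frame_rate,
            frame_rate = frame_rate,
            session_id = as.character(session_id),
            class = c("binned_matrix", "matrix", "array"))
}

#' Ensemble set: one session's NMF factorization
#'
#' Holds the non-negative factorization of a binned activity matrix into an
#' ensemble pattern (basis) matrix and an occurrence matrix. Pattern rows are
#' L2-normalized, with the norms folded into the occurrence columns so the
#' reconstruction `occurrences %*% patterns` is unchanged; all-zero pattern
#' rows are removed.
#'
#' @param patterns matrix, ensembles x neurons, non-negative, rows unit L2 norm.
#' @param occurrences matrix, time bins x ensembles, non-negative.
#' @param session_id session label.
#' @param cost final squared-Frobenius reconstruction cost.
#' @param cost_trace optional per-iteration cost vector of the winning restart.
#' @return an `ensemble_set` list with element `n_ensembles`.
#' @export
ensemble_set <- function(patterns, occurrences, session_id = "session",
                         cost = NA_real_, cost_trace = NULL) {
  patterns <- as.matrix(patterns)
  occurrences <- as.matrix(occurrences)
  if (any(patterns < 0) || any(occurrences < 0))
    stop("NMF factors must be non-negative", call. = FALSE)
  keep <- rowSums(patterns) > 0
  patterns <- patterns[keep, , drop = FALSE]
  occurrences <- occurrences[, keep, drop = FALSE]
  nrm <- sqrt(rowSums(patterns^2))
  occurrences <- sweep(occurrences, 2L, nrm, `*`)
  patterns <- patterns / nrm
  rownames(patterns) <- paste0("e", seq_len(nrow(patterns)))
  colnames(occurrences) <- rownames(patterns)
  structure(list(patterns = patterns,
                 occurrences = occurrences,
                 n_ensembles = nrow(patterns),
                 session_id = as.character(session_id),
                 cost = cost,
                 cost_trace = cost_trace),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set '%s': %d ensembles x %d neurons, %d time bins, cost %.4g>\n",
              x$session_id, x$n_ensembles, ncol(x$patterns),
              nrow(x$occurrences), x$cost))
  invisible(x)
}

#' @export
print.fluor_matrix <- function(x, ...) {
  cat(sprintf("<fluor_matrix '%s': %d frames x %d neurons @ %g Hz>\n",
              attr(x, "session_id"), nrow(x), ncol(x), attr(x, "frame_rate")))
  invisible(x)
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix '%s' [%s]: %d frames x %d neurons @ %g Hz>\n",
              attr(x, "session_id"), attr(x, "stage"), nrow(x), ncol(x),
              attr(x, "frame_rate")))
  invisible(x)
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix '%s': %d bins x %d neurons, %g ms bins>\n",
              attr(x, "session_id"), nrow(x), ncol(x),
              1000 * attr(x, "bin_duration")))
  invisible(x)
}
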