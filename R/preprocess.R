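# Preprocessing: raw fluorescence -> analysis-ready matrices.
# dF/F -> (event detection) and dF/F -> high-pass -> rectified z-score -> bins.

#' Compute \eqn{\Delta F/F}
#'
#' Normalized fluorescence change per neuron:
#' \eqn{\Delta F(t)/F_0 = (F(t) - F_0)/F_0}, where \eqn{F_0} is the neuron's
#' mean fluorescence over the entire session.
#'
#' @param raw a [fluor_matrix()].
#' @return a [trace_matrix()] at stage `"dff"`.
#' @examples
#' f <- fluor_matrix(matrix(c(8, 12), 2, 1), frame_rate = 20)
#' compute_dff(f)[, 1]  # -0.2, +0.2
#' @export
compute_dff <- function(raw) {
  stopifnot(inherits(raw, "fluor_matrix"))
  f0 <- colMeans(raw)
  bad <- which(f0 == 0)
  if (length(bad))
    stop(sprintf("F0 is zero for neuron(s): %s",
                 paste(colnames(raw)[bad], collapse = ", ")), call. = FALSE)
  vals <- sweep(sweep(unclass(raw), 2L, f0, `-`), 2L, f0, `/`)
  trace_matrix(vals, "dff", attr(raw, "frame_rate"), attr(raw, "session_id"))
}

#' Event-detection configuration
#'
#' A calcium event must exceed both an absolute amplitude threshold
#' (default 0.01 a.u.) and a multiple of the neuron's whole-session standard
#' deviation (default 3 SD). An event is the upward crossing of the joint
#' threshold; a refractory window (default 10 frames, 0.5 s at 20 Hz)
#' suppresses re-triggering within a burst.
#'
#' @param amplitude_threshold absolute \eqn{\Delta F/F} threshold, a.u.
#' @param sd_multiplier multiple of the per-neuron session SD.
#' @param refractory_frames frames after an event during which new crossings
#'   are ignored.
#' @return an `event_config` list.
#' @export
event_config <- function(amplitude_threshold = 0.01, sd_multiplier = 3,
                         refractory_frames = 10L) {
  assert_scalar_num(amplitude_threshold, "amplitude_threshold", positive = TRUE)
  assert_scalar_num(sd_multiplier, "sd_multiplier", positive = TRUE)
  refractory_frames <- as.integer(refractory_frames)
  if (refractory_frames < 0L) stop("refractory_frames must be >= 0", call. = FALSE)
  structure(list(amplitude_threshold = amplitude_threshold,
                 sd_multiplier = sd_multiplier,
                 refractory_frames = refractory_frames),
            class = "event_config")
}

# Count upward crossings of `thr` in one trace, with refractory suppression.
# A trace that starts above threshold counts as entering at frame 1.
count_crossings <- function(x, thr, refractory) {
  above <- x > thr
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rising)) return(0L)
  n <- 0L; last <- -Inf
  for (t in rising) {
    if (t - last > refractory) {
      n <- n + 1L
      last <- t
    }
  }
  n
}

#' Detect calcium events
#'
#' Counts discrete calcium transients per neuron in a \eqn{\Delta F/F} trace
#' matrix. The effective threshold for neuron *i* is
#' `max(amplitude_threshold, sd_multiplier * SD_i)` with `SD_i` computed over
#' the whole session; an event is an upward crossing from at-or-below to
#' above this threshold, consecutive suprathreshold frames count once, and
#' crossings within `refractory_frames` of the previous event are suppressed.
#' Zero-variance neurons yield zero events (reported via a message, not an
#' error).
#'
#' @param traces a [trace_matrix()] at stage `"dff"`.
#' @param cfg an [event_config()].
#' @return an `event_counts` list: `per_neuron` (named integer vector) and
#'   `per_session_mean`.
#' @export
detect_events <- function(traces, cfg = event_config()) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) != "dff")
    stop("detect_events expects dff-stage traces", call. = FALSE)
  sds <- col_sd_pop(unclass(traces))
  flat <- which(sds == 0)
  if (length(flat))
    message(sprintf("zero-variance neuron(s) %s: 0 events",
                    paste(colnames(traces)[flat], collapse = ", ")))
  counts <- vapply(seq_len(ncol(traces)), function(i) {
    if (sds[i] == 0) return(0L)
    thr <- max(cfg$amplitude_threshold, cfg$sd_multiplier * sds[i])
    count_crossings(traces[, i], thr, cfg$refractory_frames)
  }, integer(1L))
  names(counts) <- colnames(traces)
  structure(list(per_neuron = counts,
                 per_session_mean = mean(counts),
                 session_id = attr(traces, "session_id")),
            class = "event_counts")
}

#' Zero-phase high-pass filter
#'
#' Removes slow baseline fluctuation with a 4th-order Butterworth high-pass
#' applied forward and backward (zero phase, so event times are not shifted)
#' per neuron. The per-neuron mean is subtracted before filtering, which
#' rejects the DC component exactly and limits filter edge transients.
#'
#' @param traces a [trace_matrix()] (any stage; typically `"dff"`).
#' @param cutoff_hz high-pass cutoff, Hz (default 0.01).
#' @return a [trace_matrix()] at stage `"highpassed"`.
#' @export
highpass_filter <- function(traces, cutoff_hz = 0.01) {
  stopifnot(inherits(traces, "trace_matrix"))
  fr <- attr(traces, "frame_rate")
  assert_scalar_num(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (fr <= 2 * cutoff_hz)
    stop("frame_rate must exceed twice the cutoff frequency", call. = FALSE)
  # filter time constant ~ 1/(2*pi*cutoff); warn below ~3 of them
  if (nrow(traces) < 3 * fr / (2 * pi * cutoff_hz))
    warning("session shorter than ~3 filter time constants; ",
            "low-frequency attenuation will be approximate")
  bf <- signal::butter(4, cutoff_hz / (fr / 2), type = "high")
  vals <- apply(unclass(traces), 2L, function(x)
    signal::filtfilt(bf, x - mean(x)))
  trace_matrix(vals, "highpassed", fr, attr(traces, "session_id"))
}

#' Per-neuron z-score with rectification
#'
#' Standardizes each neuron's trace against its own session mean and SD, then
#' replaces negative z-scores with zero — yielding the non-negative activity
#' matrix that non-negative matrix factorization requires. Zero-SD neurons
#' become all-zero columns (reported via a message).
#'
#' @param traces a [trace_matrix()] at stage `"highpassed"`.
#' @return a [trace_matrix()] at stage `"zscored_rectified"`.
#' @export
zscore_rectify <- function(traces) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) != "highpassed")
    stop("zscore_rectify expects highpassed-stage traces", call. = FALSE)
  m <- unclass(traces)
  mu <- colMeans(m)
  sds <- col_sd_pop(m)  # population SD, the standard z-score convention
  flat <- which(sds == 0)
  if (length(flat)) {
    message(sprintf("zero-SD neuron(s) %s set to all-zero",
                    paste(colnames(traces)[flat], collapse = ", ")))
    sds[flat] <- 1  # column is constant; centering already gives zeros
  }
  z <- sweep(sweep(m, 2L, mu, `-`), 2L, sds, `/`)
  z[z < 0] <- 0
  trace_matrix(z, "zscored_rectified", attr(traces, "frame_rate"),
               attr(traces, "session_id"))
}

#' Temporal binning
#'
#' Aggregates consecutive frames into bins (default 4 frames, i.e. 200 ms at
#' 20 frames/s). Each bin is the mean of its frames, keeping values on the
#' z-score scale regardless of bin size (`agg = "sum"` is available); a
#' trailing partial bin is dropped, so the output has
#' `floor(n_frames / bin_frames)` rows.
#'
#' @param traces a [trace_matrix()] at stage `"zscored_rectified"`.
#' @param bin_frames frames per bin (>= 1).
#' @param agg `"mean"` (default) or `"sum"`.
#' @return a [binned_matrix()].
#' @export
bin_traces <- function(traces, bin_frames = 4L, agg = c("mean", "sum")) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_stage(traces) != "zscored_rectified")
    stop("bin_traces expects zscored_rectified-stage traces", call. = FALSE)
  agg <- match.arg(agg)
  bin_frames <- as.integer(bin_frames)
  if (bin_frames < 1L) stop("bin_frames must be >= 1", call. = FALSE)
  n_frames <- nrow(traces)
  if (n_frames < bin_frames)
    stop(sprintf("cannot bin %d frames into %d-frame bins", n_frames, bin_frames),
         call. = FALSE)
  n_bins <- n_frames %/% bin_frames
  m <- unclass(traces)[seq_len(n_bins * bin_frames), , drop = FALSE]
  grp <- rep(seq_len(n_bins), each = bin_frames)
  out <- rowsum(m, grp, reorder = FALSE)
  if (agg == "mean") out <- out / bin_frames
  binned_matrix(out, bin_frames, attr(traces, "frame_rate"),
                attr(traces, "session_id"))
}

#' Full preprocessing chain for ensemble extraction
#'
#' Convenience composition: \eqn{\Delta F/F} -> zero-phase high-pass ->
#' rectified z-score -> temporal bins.
#'
#' @param raw a [fluor_matrix()].
#' @param cutoff_hz high-pass cutoff, Hz.
#' @param bin_frames frames per bin.
#' @return a [binned_matrix()] ready for [extract_ensembles()].
#' @export
preprocess_session <- function(raw, cutoff_hz = 0.01, bin_frames = 4L) {
  bin_traces(zscore_rectify(highpass_filter(compute_dff(raw), cutoff_hz)),
             bin_frames)
}
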