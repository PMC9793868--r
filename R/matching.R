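# Cross-session ensemble matching: cosine similarity, matched/unmatched
# classification, the matching score MS, and the three-session reactivation
# analysis.

#' Matching configuration
#'
#' @param threshold_c cosine-similarity threshold above which (strictly) two
#'   ensemble patterns count as the same ensemble. Default 0.6.
#' @return a `match_config` list.
#' @export
match_config <- function(threshold_c = 0.6) {
  assert_scalar_num(threshold_c, "threshold_c")
  if (threshold_c <= 0 || threshold_c >= 1)
    stop("threshold_c must lie strictly in (0, 1)", call. = FALSE)
  structure(list(threshold_c = threshold_c), class = "match_config")
}

# Pull an ensembles x neurons pattern matrix out of an ensemble_set or a
# plain matrix (ground-truth memberships are accepted directly).
pattern_matrix <- function(x) {
  if (inherits(x, "ensemble_set")) x$patterns else as.matrix(x)
}

check_neuron_alignment <- function(px, py) {
  if (ncol(px) != ncol(py))
    stop("sessions disagree on neuron count", call. = FALSE)
  nx <- colnames(px); ny <- colnames(py)
  if (!is.null(nx) && !is.null(ny) && !identical(nx, ny)) {
    diff <- union(setdiff(nx, ny), setdiff(ny, nx))
    if (length(diff))
      stop(sprintf("neuron ids differ between sessions: %s",
                   paste(diff, collapse = ", ")), call. = FALSE)
    stop("neuron ids are ordered differently between sessions", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cosine similarity between all ensemble pattern pairs of two sessions
#'
#' Entry (i, j) is the normalized dot product
#' \eqn{(p_i \cdot q_j)/(\|p_i\|\|q_j\|)} between the *i*th pattern of
#' session X and the *j*th pattern of session Y; for non-negative patterns it
#' ranges from 0 (completely different) to 1 (completely the same). All-zero
#' vectors yield similarity 0 by convention. Both sessions must carry the
#' same neuron ids in the same order.
#'
#' @param x,y [ensemble_set()]s (or plain pattern matrices, ensembles x
#'   neurons).
#' @return a `similarity_matrix`: the N_X x N_Y cosine matrix with session
#'   labels attached.
#' @export
cosine_similarity_matrix <- function(x, y) {
  px <- pattern_matrix(x); py <- pattern_matrix(y)
  check_neuron_alignment(px, py)
  s <- row_cosine(px, py)
  structure(s,
            session_x = if (inherits(x, "ensemble_set")) x$session_id else "X",
            session_y = if (inherits(y, "ensemble_set")) y$session_id else "Y",
            class = c("similarity_matrix", "matrix", "array"))
}

#' Matching score between two sessions
#'
#' The matching score MS(X, Y) is the fraction of session X's ensemble
#' patterns whose best cosine similarity with any pattern of session Y
#' strictly exceeds the threshold c:
#' \deqn{MS(X,Y) = \frac{1}{N_X} \sum_i \Theta\!\left(\max_j
#'   \frac{p_i \cdot q_j}{\|p_i\|\|q_j\|} - c\right),}
#' with \eqn{\Theta} the step function. MS is asymmetric in general
#' (`MS(X, Y) != MS(Y, X)`).
#'
#' @param x,y [ensemble_set()]s or pattern matrices; X is the session whose
#'   patterns are scored.
#' @param cfg a [match_config()].
#' @return a `match_result` list: `similarity`, `matched_x` (logical per X
#'   ensemble), `matching_score`, `best_partner` (data.frame with the argmax
#'   partner index and cosine per X ensemble), `threshold_c`.
#' @examples
#' p <- diag(3)  # three orthogonal patterns
#' matching_score(p, p)$matching_score  # 1
#' @export
matching_score <- function(x, y, cfg = match_config()) {
  s <- cosine_similarity_matrix(x, y)
  if (nrow(s) < 1L || ncol(s) < 1L)
    stop("matching_score needs at least one ensemble per session", call. = FALSE)
  best_j <- apply(unclass(s), 1L, which.max)
  best_v <- unclass(s)[cbind(seq_len(nrow(s)), best_j)]
  matched <- best_v > cfg$threshold_c
  structure(list(similarity = s,
                 matched_x = matched,
                 matching_score = mean(matched),
                 best_partner = data.frame(ensemble = seq_len(nrow(s)),
                                           partner = best_j,
                                           cosine = best_v),
                 threshold_c = cfg$threshold_c),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s -> %s: MS = %.3f (%d/%d matched at c = %g)>\n",
              attr(x$similarity, "session_x"), attr(x$similarity, "session_y"),
              x$matching_score, sum(x$matched_x), length(x$matched_x),
              x$threshold_c))
  invisible(x)
}

#' Classify ensembles of both sessions as matched or unmatched
#'
#' An ensemble is *matched* iff some ensemble of the other session has cosine
#' similarity strictly above the threshold; matched ensembles are the ones
#' re-activated across sessions. Labels for X and Y come from the same
#' similarity matrix (row maxima for X, column maxima for Y).
#'
#' @inheritParams matching_score
#' @return list with logical vectors `matched_x`, `matched_y` and the
#'   `similarity` matrix.
#' @export
classify_matched <- function(x, y, cfg = match_config()) {
  s <- cosine_similarity_matrix(x, y)
  if (nrow(s) < 1L || ncol(s) < 1L)
    stop("classify_matched needs at least one ensemble per session", call. = FALSE)
  m <- unclass(s)
  list(matched_x = apply(m, 1L, max) > cfg$threshold_c,
       matched_y = apply(m, 2L, max) > cfg$threshold_c,
       similarity = s)
}

#' Three-session reactivation analysis
#'
#' Partitions the Day 1 context ensembles by whether they reactivate in the
#' rest session, then asks what percentage of each partition also reactivates
#' in the Day 2 context session:
#' `100 * (# reactivated in both rest and Day 2) / (# reactivated in rest)`
#' and likewise for the non-reactivated partition. Day 1 patterns are matched
#' independently against rest and against Day 2 (no transitivity assumed). An
#' empty partition makes the corresponding percentage undefined (`NA`), not
#' zero.
#'
#' @param day1,rest,day2 [ensemble_set()]s (or pattern matrices) with
#'   identical neuron ordering.
#' @param cfg a [match_config()].
#' @return a `reactivation_result` list: `n_reactivated_in_rest`,
#'   `n_nonreactivated_in_rest`, `pct_reactivated_also_in_day2`,
#'   `pct_nonreactivated_also_in_day2`.
#' @export
reactivation_analysis <- function(day1, rest, day2, cfg = match_config()) {
  in_rest <- classify_matched(day1, rest, cfg)$matched_x
  in_day2 <- classify_matched(day1, day2, cfg)$matched_x
  n_re <- sum(in_rest); n_non <- sum(!in_rest)
  structure(list(
    n_reactivated_in_rest = n_re,
    n_nonreactivated_in_rest = n_non,
    pct_reactivated_also_in_day2 =
      if (n_re > 0) 100 * sum(in_rest & in_day2) / n_re else NA_real_,
    pct_nonreactivated_also_in_day2 =
      if (n_non > 0) 100 * sum(!in_rest & in_day2) / n_non else NA_real_,
    threshold_c = cfg$threshold_c), class = "reactivation_result")
}

#' @export
print.reactivation_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf(paste0("<reactivation: %d rest-reactivated (%s also on Day 2), ",
                     "%d non-reactivated (%s also on Day 2)>\n"),
              x$n_reactivated_in_rest, fmt(x$pct_reactivated_also_in_day2),
              x$n_nonreactivated_in_rest, fmt(x$pct_nonreactivated_also_in_day2)))
  invisible(x)
}

#' Similarity heat map
#'
#' Renders a cross-session cosine-similarity matrix as a heat map (sessions'
#' ensemble indices on the axes, cosine in color), optionally to a PNG file.
#'
#' @param s a `similarity_matrix` (or `match_result`).
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param main plot title.
#' @return invisibly, the matrix drawn.
#' @export
plot_similarity_heatmap <- function(s, file = NULL, main = "ensemble similarity") {
  if (inherits(s, "match_result")) s <- s$similarity
  m <- unclass(s)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(0, 1), col = pal,
                  xlab = sprintf("ensembles (%s)", attr(s, "session_y") %||% "Y"),
                  ylab = sprintf("ensembles (%s)", attr(s, "session_x") %||% "X"),
                  main = main, axes = FALSE)
  graphics::axis(1, at = seq_len(ncol(m)))
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(seq_len(nrow(m))))
  graphics::box()
  invisible(m)
}
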