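#' Tolerance-zone event-detection evaluation
#'
#' A detection counts as a true positive when it falls inside a tolerance
#' zone around a ground-truth event; each truth event can be matched at
#' most once, a second in-zone detection duplicates an already counted TP
#' and is a false positive; truth events with no in-zone detection are
#' false negatives. Precision, recall and F1 follow from the counts, and
#' dataset-level F1 values are macro-averaged.
#'
#' @name evaluation
NULL

#' Match detections to ground truth within a tolerance zone
#'
#' Greedy, deterministic matching: truth events are visited in order and
#' each is assigned the nearest unassigned detection within
#' `+/- tolerance` samples (distance ties resolve to the earlier
#' detection). Unmatched truth events are FNs; every unassigned detection
#' — out of zone or duplicating a counted TP — is an FP.
#'
#' @param truth Sorted 0-based ground-truth sample indices.
#' @param detected Sorted 0-based detected sample indices.
#' @param tolerance Half-width of the tolerance zone, samples (>= 0).
#'   The default convention in [evaluate_events()] is the SSM window
#'   size `w`.
#' @return List with counts `TP`, `FP`, `FN` and `pairs`, a data frame of
#'   matched (truth, detection) sample pairs.
#' @export
#' @examples
#' match_events(c(100), c(105, 108), tolerance = 10)  # TP = 1, FP = 1
match_events <- function(truth, detected, tolerance) {
  truth <- as.numeric(truth); detected <- as.numeric(detected)
  if (is.unsorted(truth) || is.unsorted(detected))
    stop("truth and detected event lists must be sorted")
  if (!is.finite(tolerance) || tolerance < 0) stop("tolerance must be >= 0")
  assigned <- rep(FALSE, length(detected))
  pairs_t <- numeric(0); pairs_d <- numeric(0)
  for (t in truth) {
    open <- which(!assigned)
    if (!length(open)) next
    dd <- abs(detected[open] - t)
    ok <- open[dd <= tolerance]
    if (!length(ok)) next
    dd_ok <- abs(detected[ok] - t)
    best <- ok[order(dd_ok, ok)][1]   # nearest; tie -> earlier detection
    assigned[best] <- TRUE
    pairs_t <- c(pairs_t, t); pairs_d <- c(pairs_d, detected[best])
  }
  tp <- length(pairs_t)
  list(TP = tp, FP = length(detected) - tp, FN = length(truth) - tp,
       pairs = data.frame(truth = pairs_t, detected = pairs_d))
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`; any 0/0 is 0 by convention.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Named list `precision`, `recall`, `f1` (full precision; round
#'   only at presentation).
#' @export
#' @examples
#' prf(166, 16, 13)  # P 0.912, R 0.927, F1 0.920
prf <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  p <- safe_div(TP, TP + FP)
  r <- safe_div(TP, TP + FN)
  list(precision = p, recall = r, f1 = safe_div(2 * p * r, p + r))
}

#' Macro-averaged F1
#'
#' Unweighted arithmetic mean of per-dataset (unrounded) F1 values.
#'
#' @param f1_scores Non-empty numeric vector of F1 values.
#' @return The macro-averaged F1.
#' @export
macro_f1 <- function(f1_scores) {
  if (!length(f1_scores)) stop("f1_scores must be non-empty")
  mean(f1_scores)
}

#' Full tolerance-zone evaluation of a detection run
#'
#' @param truth Sorted ground-truth sample indices (or a [ts_record()],
#'   whose `events` are used).
#' @param detected Sorted detected sample indices (or an `event_set`,
#'   whose `sample_indices` are used).
#' @param tolerance Tolerance half-width in samples.
#' @return An `eval_result`: counts, metrics, matched pairs and the
#'   tolerance used.
#' @export
evaluate_events <- function(truth, detected, tolerance) {
  if (inherits(truth, "ts_record")) truth <- truth$events
  if (inherits(detected, "event_set")) detected <- detected$sample_indices
  mt <- match_events(truth, detected, tolerance)
  structure(c(mt[c("TP", "FP", "FN")], prf(mt$TP, mt$FP, mt$FN),
              list(pairs = mt$pairs, tolerance = tolerance)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> TP=%d FP=%d FN=%d | P=%.2f R=%.2f F1=%.2f (tolerance %g samples)\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f1, x$tolerance))
  invisible(x)
}

#' Recompute metrics for a table of TP/FP/FN counts
#'
#' Convenience for published count tables: applies [prf()] row-wise and
#' appends the macro-averaged F1 per grouping column.
#'
#' @param counts Data frame with columns `TP`, `FP`, `FN` (extra columns
#'   are carried through).
#' @return The data frame with `precision`, `recall`, `f1` columns added.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN") %in% names(counts)))
  met <- t(vapply(seq_len(nrow(counts)), function(i)
    unlist(prf(counts$TP[i], counts$FP[i], counts$FN[i])), numeric(3)))
  cbind(counts, as.data.frame(met))
}
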