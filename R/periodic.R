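#' Periodic segmentation via the similarity function
#'
#' In a cyclic signal every frame resembles the frames one period away, so
#' the SSM shows diagonal paths. Summing the symmetric SSM column-wise
#' gives the similarity function `sf(x) = sum_i S(i, x)`; frames at period
#' starts sit in valleys of this curve (their windows straddle the cycle
#' boundary and match fewer frames), so period-start events are detected
#' as local minima.
#'
#' @name periodic
NULL

#' Column-wise similarity function of an SSM
#'
#' @param ssm An `ssm_matrix`.
#' @param smooth Optional odd moving-average length in frames (default 0 =
#'   no smoothing), applied after summation with edge frames kept as the
#'   mean of the available neighbourhood.
#' @return A `similarity_curve`: raw column sums in `raw` (and `values`
#'   as their min-max normalization for plotting/picking machinery), plus
#'   the SSM frame metadata.
#' @export
similarity_function <- function(ssm, smooth = 0L) {
  stopifnot(inherits(ssm, "ssm_matrix"))
  sf <- colSums(ssm$values)
  smooth <- as.integer(smooth)
  if (smooth > 1L) {
    half <- smooth %/% 2L
    m <- length(sf)
    sf <- vapply(seq_len(m), function(i)
      mean(sf[max(1L, i - half):min(m, i + half)]), numeric(1))
  }
  structure(list(values = minmax_scale(sf), raw = sf,
                 window_starts = ssm$window_starts, config = ssm$config,
                 fs = ssm$fs, n_samples = ssm$n_samples),
            class = c("similarity_curve", "ssm_curve"))
}

#' Pick period-start valleys from a similarity curve
#'
#' Equivalent to [pick_peaks()] applied to the negated, min-max
#' renormalized curve: valley depth plays the role of peak height, so the
#' same strategies (`threshold` on normalized depth, `top_n`,
#' `peak_fraction`) and non-maximum suppression apply. Events are labelled
#' `periodic_valley`.
#'
#' @inheritParams pick_peaks
#' @param curve A `similarity_curve` from [similarity_function()].
#' @return An `event_set` of period-start events.
#' @export
pick_valleys <- function(curve, strategy = c("threshold", "top_n", "peak_fraction"),
                         theta = 0.3, n = NULL, fraction = NULL,
                         min_separation = 1L) {
  stopifnot(inherits(curve, "similarity_curve"))
  flipped <- curve
  flipped$values <- minmax_scale(-curve$raw)
  pick_peaks(flipped, strategy = strategy, theta = theta, n = n,
             fraction = fraction, min_separation = min_separation,
             event_type = "periodic_valley")
}

#' Rank frames by average self-similarity
#'
#' Each similarity-function value is (up to the factor m) a frame's
#' average similarity to every other frame, so uniquely shaped frames —
#' candidate anomalies — have the lowest values. This helper only returns
#' the ranking (ascending `sf`); it deliberately attaches no detection
#' threshold, as the anomaly use of the similarity function is exposed
#' but not validated.
#'
#' @param curve A `similarity_curve`.
#' @return Data frame with 0-based `frame`, `sample`, and raw `sf`,
#'   sorted ascending by `sf`.
#' @export
rank_by_similarity <- function(curve) {
  stopifnot(inherits(curve, "similarity_curve"))
  o <- order(curve$raw)
  data.frame(frame = o - 1L,
             sample = frame_to_sample(curve, o - 1L),
             sf = curve$raw[o])
}
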