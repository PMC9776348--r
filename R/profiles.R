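#' Segment similarity profiles and clustering
#'
#' A segment's similarity profile is its average similarity to every frame
#' of the recording: `P_s(c) = (1/l) * sum over the l segment rows i of
#' S(i, c)`. Two segments produced by the same underlying behaviour have
#' near-identical profiles even when their lengths differ, so profiles can
#' be compared with the Euclidean distance and clustered agglomeratively
#' to label recurring regimes.
#'
#' @name profiles
NULL

#' Build contiguous segments from detected events
#'
#' Events at frames `e1 < e2 < ... < ek` split `[0, m)` into the half-open
#' segments `[0, e1), [e1, e2), ..., [ek, m)`. No events gives the single
#' segment `[0, m)`.
#'
#' @param events An `event_set` or an integer vector of 0-based frame
#'   indices within `[0, m)`.
#' @param m Total number of frames.
#' @return List of `segment` objects (fields `start_frame`, `end_frame`,
#'   0-based half-open).
#' @export
segments_from_events <- function(events, m) {
  ev <- if (inherits(events, "event_set")) events$frame_indices else as.integer(events)
  m <- as.integer(m)
  if (anyDuplicated(ev)) stop("duplicate event frames")
  ev <- sort(ev)
  ev <- ev[ev > 0L & ev < m]
  if (length(ev) && (min(ev) < 0L || max(ev) >= m))
    stop("event frames must lie in [0, m)")
  bounds <- c(0L, ev, m)
  lapply(seq_len(length(bounds) - 1L), function(i)
    structure(list(start_frame = bounds[i], end_frame = bounds[i + 1L]),
              class = "segment"))
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> frames [%d, %d)\n", x$start_frame, x$end_frame))
  invisible(x)
}

#' Similarity profile of a segment
#'
#' @param ssm An `ssm_matrix`.
#' @param segment A `segment` (0-based half-open frame range) from
#'   [segments_from_events()].
#' @return A `similarity_profile`: `values` of length m (the column means
#'   of the segment's SSM rows) and the segment.
#' @export
similarity_profile <- function(ssm, segment) {
  stopifnot(inherits(ssm, "ssm_matrix"), inherits(segment, "segment"))
  m <- ncol(ssm$values)
  if (segment$start_frame < 0L || segment$end_frame > m ||
      segment$start_frame >= segment$end_frame)
    stop("segment must be a non-empty frame range within the matrix")
  rows <- (segment$start_frame + 1L):segment$end_frame
  structure(list(values = colMeans(ssm$values[rows, , drop = FALSE]),
                 segment = segment),
            class = "similarity_profile")
}

#' Cluster segments by their similarity profiles
#'
#' Pairwise Euclidean distances between profiles feed agglomerative
#' hierarchical clustering; the tree is cut either at `k` clusters or at
#' distance `distance_cut`.
#'
#' @param profiles List of `similarity_profile` objects (>= 2).
#' @param linkage `"average"` (UPGMA, default), `"complete"` or
#'   `"single"`.
#' @param k Number of clusters (exclusive with `distance_cut`).
#' @param distance_cut Merge-height cut (exclusive with `k`).
#' @param scale_profiles Z-score each profile before computing distances
#'   (default `FALSE`: raw profile values are compared).
#' @return List with `labels` (integer cluster per segment, numbered by
#'   first appearance), `tree` (the `hclust` merge tree), `distances`
#'   (the `dist` object), and `segments`.
#' @export
cluster_segments <- function(profiles, linkage = c("average", "complete", "single"),
                             k = NULL, distance_cut = NULL,
                             scale_profiles = FALSE) {
  linkage <- match.arg(linkage)
  if (length(profiles) < 2L) stop("need at least 2 profiles to cluster")
  if (is.null(k) == is.null(distance_cut))
    stop("supply exactly one of k or distance_cut")
  if (!is.null(k) && k > length(profiles))
    stop("k exceeds the number of profiles")
  pm <- t(vapply(profiles, `[[`, numeric(length(profiles[[1]]$values)), "values"))
  if (scale_profiles) {
    mu <- rowMeans(pm); s <- apply(pm, 1L, stats::sd); s[s == 0] <- 1
    pm <- (pm - mu) / s
  }
  d <- stats::dist(pm, method = "euclidean")
  tree <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k)) stats::cutree(tree, k = k)
            else stats::cutree(tree, h = distance_cut)
  # renumber by first appearance so labels are deterministic
  labels <- match(labels, unique(labels))
  list(labels = as.integer(labels), tree = tree, distances = d,
       segments = lapply(profiles, `[[`, "segment"))
}

#' Serialize a segment-cluster merge tree to JSON
#'
#' Writes the agglomeration (merge pairs, heights, leaf order and labels)
#' as structured text for dendrogram rendering elsewhere.
#'
#' @param clustering Result of [cluster_segments()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_merge_tree <- function(clustering, path) {
  tree <- clustering$tree
  segs <- clustering$segments
  jsonlite::write_json(list(
    merge = apply(tree$merge, 1L, identity, simplify = FALSE),
    height = tree$height,
    order = tree$order,
    labels = clustering$labels,
    segments = list(
      start_frame = vapply(segs, `[[`, integer(1), "start_frame"),
      end_frame = vapply(segs, `[[`, integer(1), "end_frame"))
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
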