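#' Checkerboard-kernel novelty detection
#'
#' A transition between two homogeneous blocks on the SSM diagonal looks
#' like a 2 x 2 checkerboard: high within-block similarity, low
#' cross-block similarity. Correlating a Gaussian-tapered checkerboard
#' kernel along the diagonal therefore yields a curve — the novelty
#' function — whose peaks mark change points.
#'
#' @name novelty
NULL

#' Build the Gaussian-tapered checkerboard kernel
#'
#' Over offsets `a, b in [-L, L]` the sign kernel is
#' `K_N(a, b) = sign(a) * sign(b)` (+1 on the diagonal quadrants, -1 on
#' the anti-diagonal quadrants, 0 on the centre row/column). It is tapered
#' by the radially symmetric Gaussian
#' `phi(a, b) = exp(-(a^2 + b^2) / (2 * L^2 * sigma^2))`, giving
#' `K_G = phi * K_N`; `sigma` is therefore dimensionless relative to the
#' kernel half-size `L`. With `normalize = TRUE` the kernel is divided by
#' `sum(|K_G|)` so novelty amplitudes are comparable across kernel sizes.
#'
#' @param L Half-size of the kernel (section size, >= 1); total size is
#'   `D = 2L + 1`.
#' @param sigma Gaussian taper parameter (> 0), relative to `L`.
#' @param normalize Divide by `sum(|K_G|)` (default `TRUE`).
#' @return An object of class `checkerboard_kernel` with fields `L`,
#'   `sigma`, `D`, `normalized` and the `D x D` matrix `values`.
#' @export
#' @examples
#' build_kernel(1, 1, normalize = FALSE)$values  # tapered 3 x 3 sign grid
build_kernel <- function(L, sigma = 0.5, normalize = TRUE) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("kernel half-size L must be >= 1")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  off <- seq.int(-L, L)
  kn <- outer(sign(off), sign(off))
  phi <- exp(-outer(off^2, off^2, "+") / (2 * L^2 * sigma^2))
  kg <- phi * kn
  if (normalize) kg <- kg / sum(abs(kg))
  structure(list(L = L, sigma = sigma, D = 2L * L + 1L,
                 normalized = normalize, values = kg),
            class = "checkerboard_kernel")
}

#' @export
print.checkerboard_kernel <- function(x, ...) {
  cat(sprintf("<checkerboard_kernel> D=%d (L=%d), sigma=%g%s\n",
              x$D, x$L, x$sigma, if (x$normalized) ", amplitude-normalized" else ""))
  invisible(x)
}

#' Correlate the kernel along the SSM diagonal
#'
#' For every frame `c`,
#' `nf(c) = sum over a, b in [-L, L] of K_G(a, b) * S(c + a, c + b)`,
#' with the SSM zero-padded by `L` frames on all sides so the curve is
#' defined at every frame. The first and last `L` values are set to zero:
#' there the kernel overlaps the padding, and on a constant similarity
#' field the padding would otherwise fake a change point at each border.
#' The raw curve is min-max normalized to
#' `[0, 1]` (an all-constant raw curve maps to all zeros); the raw values
#' stay available in the `raw` field.
#'
#' @param ssm An `ssm_matrix`.
#' @param kernel A `checkerboard_kernel`; must not be larger than the
#'   matrix (`D <= m`).
#' @return A `novelty_curve`: `values` (normalized, in `[0, 1]`), `raw`,
#'   and the frame metadata of the SSM.
#' @export
novelty_function <- function(ssm, kernel) {
  stopifnot(inherits(ssm, "ssm_matrix"), inherits(kernel, "checkerboard_kernel"))
  m <- ncol(ssm$values)
  L <- kernel$L
  if (kernel$D > m)
    stop(sprintf("kernel size D=%d exceeds matrix size m=%d", kernel$D, m))
  pad <- matrix(0, m + 2L * L, m + 2L * L)
  pad[(L + 1L):(L + m), (L + 1L):(L + m)] <- ssm$values
  raw <- vapply(seq_len(m), function(c) {
    sum(kernel$values * pad[c:(c + 2L * L), c:(c + 2L * L)])
  }, numeric(1))
  # the kernel support lies fully inside the matrix only L frames in from
  # either border; border values are zeroed (padding artefacts otherwise
  # masquerade as change points there)
  raw[c(seq_len(L), m - seq_len(L) + 1L)] <- 0
  structure(list(values = minmax_scale(raw), raw = raw,
                 window_starts = ssm$window_starts, config = ssm$config,
                 fs = ssm$fs, n_samples = ssm$n_samples),
            class = c("novelty_curve", "ssm_curve"))
}

minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.ssm_curve <- function(x, ...) {
  cat(sprintf("<%s> %d frame(s), range [%.3g, %.3g]\n",
              class(x)[1], length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

new_event_set <- function(frames, scores, frame_meta, event_type) {
  o <- order(frames)
  frames <- as.integer(frames[o]); scores <- scores[o]
  structure(list(frame_indices = frames,
                 sample_indices = frame_to_sample(frame_meta, frames),
                 scores = scores, event_type = event_type,
                 fs = frame_meta$fs),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d %s event(s)\n", length(x$frame_indices), x$event_type))
  if (length(x$frame_indices))
    print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.event_set <- function(x, ...) {
  data.frame(frame = x$frame_indices, sample = x$sample_indices,
             time_s = x$sample_indices / x$fs, score = x$scores,
             type = rep(x$event_type, length.out = length(x$frame_indices)))
}

#' Pick change-point peaks from a novelty curve
#'
#' Candidates are the strict local maxima of the normalized curve
#' (`values[i] > values[i - 1]` and `> values[i + 1]`; endpoints are never
#' candidates). One filtering strategy is then applied:
#' * `threshold`: keep candidates with normalized height `>= theta`;
#' * `top_n`: keep the `n` highest candidates;
#' * `peak_fraction`: keep the top `fraction` of candidates by height
#'   (`ceiling(fraction * n_candidates)` peaks).
#'
#' Finally, greedy non-maximum suppression removes any surviving peak
#' closer than `min_separation` frames to a higher accepted peak (height
#' ties resolve to the earlier frame).
#'
#' @param curve A `novelty_curve` (or any `ssm_curve` with normalized
#'   `values`).
#' @param strategy `"threshold"`, `"top_n"` or `"peak_fraction"`.
#' @param theta Height threshold in `[0, 1]` (strategy `"threshold"`).
#' @param n Number of peaks to keep (strategy `"top_n"`).
#' @param fraction Fraction of candidates to keep, in `(0, 1]`
#'   (strategy `"peak_fraction"`).
#' @param min_separation Minimum distance between accepted peaks, frames.
#' @param event_type Label stored on the result.
#' @return An `event_set` with frame indices, mapped sample indices,
#'   scores (curve heights) and the event type, sorted by frame.
#' @export
pick_peaks <- function(curve, strategy = c("threshold", "top_n", "peak_fraction"),
                       theta = 0.3, n = NULL, fraction = NULL,
                       min_separation = 1L, event_type = "novelty_peak") {
  strategy <- match.arg(strategy)
  v <- curve$values
  m <- length(v)
  min_separation <- as.integer(min_separation)
  if (is.na(min_separation) || min_separation < 1L)
    stop("min_separation must be >= 1 frame")
  cand <- if (m < 3L) integer(0) else
    which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L  # 1-based interior
  keep <- switch(strategy,
    threshold = {
      if (!is.finite(theta) || theta < 0 || theta > 1)
        stop("theta must be in [0, 1]")
      cand[v[cand] >= theta]
    },
    top_n = {
      if (is.null(n) || n < 1) stop("top_n strategy requires n >= 1")
      cand[order(-v[cand], cand)][seq_len(min(n, length(cand)))]
    },
    peak_fraction = {
      if (is.null(fraction) || fraction <= 0 || fraction > 1)
        stop("peak_fraction strategy requires fraction in (0, 1]")
      n_keep <- if (length(cand)) ceiling(fraction * length(cand)) else 0L
      cand[order(-v[cand], cand)][seq_len(n_keep)]
    })
  # non-maximum suppression: visit by height (ties: earlier frame), accept
  # if no accepted peak lies within min_separation frames
  keep <- keep[order(-v[keep], keep)]
  accepted <- integer(0)
  for (p in keep)
    if (!length(accepted) || all(abs(accepted - p) >= min_separation))
      accepted <- c(accepted, p)
  new_event_set(accepted - 1L, v[accepted], curve, event_type)
}
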