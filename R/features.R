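#' Sliding-window feature extraction and the doubly normalized feature matrix
#'
#' A window of `w` samples slides over each channel with hop
#' `max(1, round(w * (1 - overlap_frac)))`; per window and channel a
#' registry of statistical, temporal and spectral features is evaluated.
#' The features are stacked into the feature matrix FM (rows = feature
#' series per channel, columns = frames), which is then doubly normalized:
#' each row is z-scored, then each column is scaled to unit Euclidean norm
#' so that the plain dot product of two columns is their cosine similarity.
#'
#' @name features
NULL

#' Windowing configuration
#'
#' @param w Window size in samples (>= 2).
#' @param overlap_frac Fractional overlap between consecutive windows, in
#'   `[0, 1)`. The hop (step) in samples is derived as
#'   `max(1, round(w * (1 - overlap_frac)))`.
#' @return An object of class `windowing_config` with fields `w`,
#'   `overlap_frac`, `hop`.
#' @export
#' @examples
#' windowing_config(250, 0.95)  # hop 12
windowing_config <- function(w, overlap_frac = 0) {
  w <- as.integer(w)
  if (is.na(w) || w < 2L) stop("window size w must be >= 2 samples")
  if (!is.finite(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  hop <- max(1L, as.integer(round(w * (1 - overlap_frac))))
  structure(list(w = w, overlap_frac = overlap_frac, hop = hop),
            class = "windowing_config")
}

#' Window start indices for a signal of length n
#'
#' Starts are `0, hop, 2*hop, ...` (0-based); any incomplete trailing
#' window is discarded, so every window `[s, s + w)` lies inside `[0, n)`.
#'
#' @param n Signal length in samples.
#' @param config A [windowing_config()].
#' @return Integer vector of 0-based window start indices, length
#'   `floor((n - w) / hop) + 1`.
#' @export
sliding_windows <- function(n, config) {
  stopifnot(inherits(config, "windowing_config"))
  n <- as.integer(n)
  if (n < config$w) stop("signal shorter than window")
  m <- (n - config$w) %/% config$hop + 1L
  config$hop * (seq_len(m) - 1L)
}

#' Map frame indices to sample indices (window centres)
#'
#' @param frame_meta A `feature_matrix`, `ssm_matrix`, or any object with
#'   `window_starts` and `config` fields.
#' @param frames 0-based frame indices (default: all frames).
#' @return 0-based sample indices of the window centres.
#' @export
frame_to_sample <- function(frame_meta, frames = NULL) {
  starts <- frame_meta$window_starts
  if (is.null(frames)) frames <- seq_along(starts) - 1L
  if (any(frames < 0L | frames >= length(starts)))
    stop("frame index out of range")
  as.integer(starts[frames + 1L] + frame_meta$config$w %/% 2L)
}

#' @rdname frame_to_sample
#' @param samples 0-based sample indices to map to the nearest frame
#'   (by window centre), clamped to the frame range.
#' @export
sample_to_frame <- function(frame_meta, samples) {
  ctr <- frame_to_sample(frame_meta)
  vapply(samples, function(s) which.min(abs(ctr - s)) - 1L, integer(1))
}

# ---- feature registry -------------------------------------------------------

# Population central moment helpers; all features map a length-w numeric
# window (plus fs for spectral ones) to one scalar.
pop_var <- function(x) mean((x - mean(x))^2)

# Periodogram of the mean-removed window at positive frequencies j*fs/w,
# j = 1..floor(w/2).
window_periodogram <- function(x, fs) {
  w <- length(x)
  X <- stats::fft(x - mean(x))
  j <- seq_len(w %/% 2L)
  list(freq = j * fs / w, power = Mod(X[j + 1L])^2)
}

feature_defs <- function() {
  list(
    mean = function(x, fs) mean(x),
    std = function(x, fs) sqrt(pop_var(x)),
    var = function(x, fs) pop_var(x),
    median = function(x, fs) stats::median(x),
    min = function(x, fs) min(x),
    max = function(x, fs) max(x),
    peak_to_peak = function(x, fs) max(x) - min(x),
    skewness = function(x, fs) {
      m2 <- pop_var(x)
      mean((x - mean(x))^3) / m2^1.5      # NaN on flat windows, mapped to 0
    },
    kurtosis = function(x, fs) {
      m2 <- pop_var(x)
      mean((x - mean(x))^4) / m2^2
    },
    iqr = function(x, fs) unname(diff(stats::quantile(x, c(0.25, 0.75)))),
    rms = function(x, fs) sqrt(mean(x^2)),
    abs_energy = function(x, fs) sum(x^2),
    mean_abs_diff = function(x, fs) mean(abs(diff(x))),
    zero_cross = function(x, fs) zero_crossings(x),
    slope = function(x, fs) {
      t <- seq_along(x) - 1
      sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
    },
    autocorr_lag1 = function(x, fs) {
      xc <- x - mean(x)
      w <- length(x)
      sum(xc[-w] * xc[-1]) / sum(xc^2)    # NaN on flat windows
    },
    hist_entropy = function(x, fs) {
      if (max(x) == min(x)) return(0)
      cuts <- findInterval(x, seq(min(x), max(x), length.out = 11L),
                           rightmost.closed = TRUE)
      p <- tabulate(cuts, nbins = 10L) / length(x)
      p <- p[p > 0]
      -sum(p * log(p))
    },
    spectral_centroid = function(x, fs) {
      pg <- window_periodogram(x, fs)
      sum(pg$freq * pg$power) / sum(pg$power)
    },
    spectral_spread = function(x, fs) {
      pg <- window_periodogram(x, fs)
      ctr <- sum(pg$freq * pg$power) / sum(pg$power)
      sqrt(sum((pg$freq - ctr)^2 * pg$power) / sum(pg$power))
    },
    median_freq = function(x, fs) {
      pg <- window_periodogram(x, fs)
      tot <- sum(pg$power)
      if (tot == 0) return(NaN)
      pg$freq[which(cumsum(pg$power) >= tot / 2)[1]]
    },
    max_power_freq = function(x, fs) {
      pg <- window_periodogram(x, fs)
      if (sum(pg$power) == 0) return(NaN)
      pg$freq[which.max(pg$power)]
    },
    spectral_entropy = function(x, fs) {
      pg <- window_periodogram(x, fs)
      p <- pg$power / sum(pg$power)
      p <- p[p > 0]
      -sum(p * log(p)) / log(length(pg$power))
    }
  )
}

# Sign changes between consecutive samples; exact zeros carry the previous
# sign forward so a tangential touch is not double-counted.
zero_crossings <- function(x) {
  s <- sign(x)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  sum(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
}

#' Names of the registered window features
#'
#' The default per-channel feature set spans the statistical (moments,
#' order statistics), temporal (differences, zero crossings, trend,
#' autocorrelation, histogram entropy) and spectral (periodogram moments,
#' median/peak frequency, spectral entropy) domains.
#'
#' @return Character vector of feature names, in registry order.
#' @export
feature_names <- function() names(feature_defs())

#' Extract windowed features into a feature matrix
#'
#' @param record A [ts_record()].
#' @param config A [windowing_config()].
#' @param feature_set Character vector of registry feature names
#'   (default: the full registry, see [feature_names()]).
#' @return An unnormalized `feature_matrix`: fields `values`
#'   ((r*k) x m matrix), `feature_names` (`<feature>_<channel>` labels,
#'   ordered channel-major: for each channel, each feature in registry
#'   order), `window_starts` (0-based), `config`, `fs`, `channel_names`,
#'   `n_samples`, `normalized = FALSE`. Non-finite feature outputs
#'   (e.g. moment ratios on flat windows) are replaced by 0 with a warning.
#' @export
extract_features <- function(record, config, feature_set = feature_names()) {
  stopifnot(inherits(record, "ts_record"), inherits(config, "windowing_config"))
  if (!length(feature_set)) stop("feature_set must be non-empty")
  defs <- feature_defs()
  unknown <- setdiff(feature_set, names(defs))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  defs <- defs[feature_set]
  starts <- sliding_windows(nrow(record$samples), config)
  m <- length(starts)
  k <- ncol(record$samples)
  r <- length(defs)
  vals <- matrix(0, nrow = r * k, ncol = m)
  rn <- character(r * k)
  for (ch in seq_len(k)) {
    sig <- record$samples[, ch]
    rows <- (ch - 1L) * r + seq_len(r)
    rn[rows] <- paste0(feature_set, "_", record$channel_names[ch])
    for (j in seq_len(m)) {
      win <- sig[(starts[j] + 1L):(starts[j] + config$w)]
      vals[rows, j] <- vapply(defs, function(f) f(win, record$fs), numeric(1))
    }
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning(sprintf("%d non-finite feature value(s) replaced by 0", sum(bad)))
    vals[bad] <- 0
  }
  structure(list(values = vals, feature_names = rn,
                 window_starts = as.integer(starts), config = config,
                 fs = record$fs, channel_names = record$channel_names,
                 n_samples = nrow(record$samples), normalized = FALSE),
            class = "feature_matrix")
}

#' Doubly normalize a feature matrix
#'
#' Step 1: each row (feature series) is z-normalized with the population
#' standard deviation; zero-variance rows become all-zero (with a warning)
#' so uninformative features drop out of the similarity. Step 2: each
#' column (frame feature vector) is scaled to unit Euclidean norm;
#' all-zero columns are left all-zero (with a warning). After both steps
#' the dot product of two columns is their cosine similarity.
#'
#' @param fm An unnormalized `feature_matrix` from [extract_features()].
#' @return The normalized `feature_matrix` (`normalized = TRUE`).
#' @export
normalize_fm <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (isTRUE(fm$normalized)) stop("feature matrix is already normalized")
  v <- fm$values
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  flat <- sd_pop == 0
  if (any(flat))
    warning(sprintf("%d zero-variance feature row(s) set to zero", sum(flat)))
  sd_pop[flat] <- 1
  v <- (v - mu) / sd_pop
  v[flat, ] <- 0
  norms <- sqrt(colSums(v^2))
  zero_col <- norms == 0
  if (any(zero_col))
    warning(sprintf("%d all-zero frame column(s) left unnormalized", sum(zero_col)))
  norms[zero_col] <- 1
  fm$values <- sweep(v, 2L, norms, "/")
  fm$normalized <- TRUE
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d feature row(s) x %d frame(s); w=%d hop=%d fs=%g; %s\n",
              nrow(x$values), ncol(x$values), x$config$w, x$config$hop, x$fs,
              if (isTRUE(x$normalized)) "normalized" else "unnormalized"))
  invisible(x)
}
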