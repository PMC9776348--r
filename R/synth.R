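#' Labelled synthetic biosignal generator
#'
#' Generators for uni- and multichannel test signals with known structure:
#' piecewise regimes differing in mean/variance/frequency (activity-like),
#' periodic waveforms with a known period (pressure/cardiac-like), and noise
#' episodes injected at a stated SNR (noise-stress-like). Every generated
#' record carries its ground-truth event positions, so each downstream stage
#' (features, SSM, novelty, periodicity, clustering, evaluation) can be
#' validated without external data.
#'
#' @name synth
NULL

#' Construct a regime specification
#'
#' One homogeneous regime of a piecewise signal: Gaussian noise with the
#' given mean and standard deviation plus an optional sinusoidal component
#' `amplitude * sin(2*pi*frequency*t)`.
#'
#' @param length Regime length in samples (>= 1).
#' @param mean Baseline level, signal units.
#' @param std Standard deviation of the Gaussian component (>= 0).
#' @param frequency Oscillation frequency in Hz (0 = no oscillation).
#' @param amplitude Oscillation amplitude, signal units (>= 0).
#' @return An object of class `regime_spec`.
#' @export
#' @examples
#' regime_spec(500, mean = 3, std = 1)
#' regime_spec(300, frequency = 5, amplitude = 1, std = 0.1)
regime_spec <- function(length, mean = 0, std = 1, frequency = 0, amplitude = 0) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("regime length must be >= 1 sample")
  vals <- c(mean = mean, std = std, frequency = frequency, amplitude = amplitude)
  if (any(!is.finite(vals)))
    stop("regime parameters must be finite")
  if (std < 0) stop("std must be >= 0")
  if (frequency < 0) stop("frequency must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(length = length, mean = mean, std = std,
                 frequency = frequency, amplitude = amplitude),
            class = "regime_spec")
}

#' Construct a time-series record
#'
#' The package's container for a sampled signal: an n x k matrix (one column
#' per channel), the sampling rate, channel names, and optional ground-truth
#' event positions as 0-based sample indices. Invariants (finite samples,
#' strictly increasing events inside `[0, n)`) are asserted on construction.
#'
#' @param samples Numeric matrix (n x k) or vector (coerced to one column).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of k channel labels;
#'   defaults to `ch0..ch(k-1)`.
#' @param events Optional integer vector of ground-truth event sample
#'   indices, 0-based, strictly increasing, within `[0, n)`.
#' @return An object of class `ts_record` with fields `samples`, `fs`,
#'   `channel_names`, `events`, and `n`/`k` accessors via `dim`.
#' @export
ts_record <- function(samples, fs, channel_names = NULL, events = integer(0)) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz")
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stop("samples must be a non-empty n x k matrix")
  if (any(!is.finite(samples))) stop("samples contain NaN/Inf")
  n <- nrow(samples)
  k <- ncol(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(k) - 1L)
  if (length(channel_names) != k) stop("channel_names must have one label per column")
  events <- as.integer(events)
  if (length(events)) {
    if (is.unsorted(events, strictly = TRUE))
      stop("ground-truth events must be strictly increasing")
    if (min(events) < 0L || max(events) >= n)
      stop("ground-truth events must lie in [0, n)")
  }
  colnames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 events = events),
            class = "ts_record")
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf("<ts_record> %d samples x %d channel(s) @ %g Hz (%.3f s), %d ground-truth event(s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs, length(x$events)))
  invisible(x)
}

#' @export
dim.ts_record <- function(x) dim(x$samples)

# One documented pseudo-random stream per generator call: a local L'Ecuyer-free
# scope using the supplied integer seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a piecewise-regime signal
#'
#' Concatenates regimes, each contributing
#' `amplitude * sin(2*pi*frequency*t) + N(mean, std^2)` per sample, with the
#' cumulative regime boundaries (excluding 0 and n) as ground-truth change
#' points. All channels share the regime parameters; each channel draws its
#' own noise, so channels are statistically exchangeable replicates.
#'
#' @param regimes List of [regime_spec()] objects (>= 1).
#' @param fs Sampling rate in Hz.
#' @param channels Number of channels k (>= 1).
#' @param seed Integer seed; identical arguments + seed give bit-identical
#'   records.
#' @return A [ts_record()] with `events` at the regime boundaries.
#' @export
#' @examples
#' r <- make_piecewise_signal(list(regime_spec(500), regime_spec(500, mean = 3)),
#'                            fs = 100, seed = 1)
#' r$events  # 500
make_piecewise_signal <- function(regimes, fs = 100, channels = 1L, seed = 0L) {
  if (!length(regimes)) stop("at least one regime is required")
  regimes <- lapply(regimes, function(r) {
    if (!inherits(r, "regime_spec"))
      stop("each regime must be a regime_spec")
    r
  })
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  channels <- as.integer(channels)
  if (channels < 1L) stop("channels must be >= 1")
  lens <- vapply(regimes, `[[`, integer(1), "length")
  n <- sum(lens)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  with_seed(seed, {
    x <- matrix(0, nrow = n, ncol = channels)
    for (i in seq_along(regimes)) {
      r <- regimes[[i]]
      idx <- seq.int(starts[i] + 1L, starts[i] + r$length)
      t_sec <- (idx - 1L) / fs
      det <- r$mean + r$amplitude * sin(2 * pi * r$frequency * t_sec)
      for (ch in seq_len(channels))
        x[idx, ch] <- det + stats::rnorm(r$length, 0, r$std)
    }
    events <- cumsum(lens)
    events <- events[events < n]   # exclude n (and 0 never appears)
    ts_record(x, fs = fs, events = as.integer(events))
  })
}

#' Generate a periodic signal with known period
#'
#' Repeats one template cycle `n_periods` times and adds white Gaussian
#' noise. Ground-truth events mark the interior period starts (multiples of
#' `period`, excluding 0 and n).
#'
#' @param period Period in samples (>= 4).
#' @param n_periods Number of cycles (>= 2).
#' @param template Cycle shape: `"sine"`, `"gaussian_pulse"` (one pulse per
#'   cycle, width period/10), or `"spike_train"` (one unit spike per cycle).
#' @param noise_std Standard deviation of the additive noise.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A [ts_record()] of length `period * n_periods`.
#' @export
make_periodic_signal <- function(period, n_periods, template = c("sine", "gaussian_pulse", "spike_train"),
                                 noise_std = 0, fs = 100, seed = 0L) {
  period <- as.integer(period)
  n_periods <- as.integer(n_periods)
  if (is.na(period) || period < 4L) stop("period must be >= 4 samples")
  if (is.na(n_periods) || n_periods < 2L) stop("n_periods must be >= 2")
  template <- match.arg(template)
  if (noise_std < 0) stop("noise_std must be >= 0")
  ph <- seq_len(period) - 1L
  cycle <- switch(template,
    sine = sin(2 * pi * ph / period),
    gaussian_pulse = exp(-0.5 * ((ph - period / 4) / (period / 10))^2),
    spike_train = as.numeric(ph == period %/% 4))
  n <- period * n_periods
  base <- rep(cycle, n_periods)
  with_seed(seed, {
    x <- base + if (noise_std > 0) stats::rnorm(n, 0, noise_std) else 0
    events <- period * seq_len(n_periods - 1L)
    ts_record(x, fs = fs, events = as.integer(events))
  })
}

# mean-square power over a 0-based half-open sample interval
interval_power <- function(x, interval) {
  idx <- seq.int(interval[1] + 1L, interval[2])
  mean(x[idx, , drop = FALSE]^2)
}

#' Inject noise at a target SNR over an interval
#'
#' Adds noise to `record` inside the half-open sample interval
#' `[start, end)` so that the realized signal-to-noise power ratio over the
#' interval is exactly `snr_db` (the drawn noise is rescaled to the measured
#' per-interval powers, so calibration is exact up to floating point).
#' The interval endpoints are appended to the ground-truth events,
#' mirroring the convention that entering and leaving a noise episode are
#' both change points. `snr_db = Inf` is the no-noise passthrough.
#'
#' @param record A [ts_record()].
#' @param snr_db Target SNR in dB: `10*log10(P_signal/P_noise)` measured on
#'   the interval. `Inf` returns the record unchanged.
#' @param interval Length-2 vector `c(start, end)`, 0-based half-open, in
#'   samples.
#' @param noise_kind `"white"` (Gaussian), `"lowfreq_wander"` (random-phase
#'   slow sinusoid drift, ~0.3 Hz), or `"burst"` (Gaussian with 10x std —
#'   an EMG-activation-like surrogate; the 10x factor is folded into the
#'   SNR rescaling, so it shapes nothing for white-within-interval noise
#'   but is kept for API symmetry).
#' @param seed Integer seed.
#' @return A [ts_record()] with noise added on the interval and events
#'   `{start, end}` merged into the ground truth (sorted, deduplicated;
#'   boundaries at 0 or n are dropped since no transition exists there).
#' @export
add_noise_at_snr <- function(record, snr_db, interval,
                             noise_kind = c("white", "lowfreq_wander", "burst"),
                             seed = 0L) {
  stopifnot(inherits(record, "ts_record"))
  noise_kind <- match.arg(noise_kind)
  n <- nrow(record$samples)
  interval <- as.integer(interval)
  if (length(interval) != 2L || interval[1] >= interval[2])
    stop("interval must be a non-empty [start, end) pair")
  if (interval[1] < 0L || interval[2] > n)
    stop("interval must lie within [0, n)")
  if (is.na(snr_db)) stop("snr_db must be finite or +Inf")
  if (is.infinite(snr_db) && snr_db > 0) return(record)
  if (!is.finite(snr_db)) stop("snr_db must be finite or +Inf")
  len <- interval[2] - interval[1]
  idx <- seq.int(interval[1] + 1L, interval[2])
  k <- ncol(record$samples)
  with_seed(seed, {
    noise <- switch(noise_kind,
      white = matrix(stats::rnorm(len * k), len, k),
      burst = matrix(stats::rnorm(len * k, sd = 10), len, k),
      lowfreq_wander = {
        t_sec <- (idx - 1L) / record$fs
        vapply(seq_len(k), function(ch)
          sin(2 * pi * 0.3 * t_sec + stats::runif(1, 0, 2 * pi)),
          numeric(len))
      })
    noise <- matrix(noise, len, k)
    p_sig <- interval_power(record$samples, interval)
    p_noise_raw <- mean(noise^2)
    if (p_noise_raw == 0) stop("degenerate zero-power noise draw")
    # target noise power: P_sig / 10^(snr/10); rescale the draw exactly
    target <- p_sig / 10^(snr_db / 10)
    noise <- noise * sqrt(target / p_noise_raw)
    x <- record$samples
    x[idx, ] <- x[idx, ] + noise
    ev <- sort(unique(c(record$events, interval[interval > 0L & interval < n])))
    ts_record(x, fs = record$fs, channel_names = record$channel_names,
              events = as.integer(ev))
  })
}

#' Standard activity-like validation record
#'
#' The package's frozen multichannel validation fixture: a 6-channel
#' (6-axis inertial-unit-like) record of four 7.5 s regimes at 100 Hz —
#' two static postures differing in baseline by 6 noise standard
#' deviations, then two dynamic activities with 5 Hz and 15 Hz
#' oscillations (frequency ratio 3, amplitude 3) over the second/first
#' baseline. Ground truth: the three regime transitions.
#'
#' @param seed Integer seed.
#' @return A [ts_record()] (n = 3000, k = 6, fs = 100, 3 events).
#' @export
make_activity_record <- function(seed = 0L) {
  make_piecewise_signal(list(
    regime_spec(750, mean = 0),
    regime_spec(750, mean = 6),
    regime_spec(750, mean = 6, frequency = 5, amplitude = 3),
    regime_spec(750, mean = 0, frequency = 15, amplitude = 3)),
    fs = 100, channels = 6L, seed = seed)
}

#' Measure SNR over an interval
#'
#' Utility for checking injected-noise calibration:
#' `10*log10(P_reference / P_difference)` where powers are mean squares over
#' the 0-based half-open interval.
#'
#' @param clean,noisy Two [ts_record()]s of identical shape.
#' @param interval `c(start, end)` 0-based half-open sample interval.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy, interval) {
  stopifnot(inherits(clean, "ts_record"), inherits(noisy, "ts_record"))
  p_sig <- interval_power(clean$samples, interval)
  p_noise <- interval_power(noisy$samples - clean$samples, interval)
  10 * log10(p_sig / p_noise)
}
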