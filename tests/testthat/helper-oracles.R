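# Independent brute-force oracles: literal loop evaluations of the defining
# formulas, kept free of the package's computation paths.

# nested-loop novelty: nf(c) = sum_{a,b in [-L,L]} K(a,b) * S(c+a, c+b),
# zero outside the matrix, with the first/last L values zeroed (the border
# convention); indices 1-based internally
oracle_novelty <- function(S, K, L) {
  m <- nrow(S)
  out <- numeric(m)
  for (c in seq_len(m)) {
    acc <- 0
    for (a in -L:L) for (b in -L:L) {
      i <- c + a; j <- c + b
      if (i >= 1 && i <= m && j >= 1 && j <= m)
        acc <- acc + K[a + L + 1, b + L + 1] * S[i, j]
    }
    out[c] <- acc
  }
  out[c(seq_len(L), m - seq_len(L) + 1)] <- 0
  out
}

oracle_similarity <- function(S) {
  m <- ncol(S)
  out <- numeric(m)
  for (x in seq_len(m)) for (i in seq_len(m)) out[x] <- out[x] + S[i, x]
  out
}

oracle_profile <- function(S, rows) {
  m <- ncol(S)
  out <- numeric(m)
  for (cc in seq_len(m)) {
    for (i in rows) out[cc] <- out[cc] + S[i, cc]
    out[cc] <- out[cc] / length(rows)
  }
  out
}

oracle_cosine_ssm <- function(FM) {
  m <- ncol(FM)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    S[i, j] <- sum(FM[, i] * FM[, j])
  S
}

oracle_kernel <- function(L, sigma) {
  D <- 2 * L + 1
  K <- matrix(0, D, D)
  for (a in -L:L) for (b in -L:L)
    K[a + L + 1, b + L + 1] <-
      sign(a) * sign(b) * exp(-(a^2 + b^2) / (2 * L^2 * sigma^2))
  K
}

# explicit-DFT direct-formula feature oracle (independent of the registry
# implementations: DFT by summation, manual quantiles, manual moments)
oracle_features <- function(x, fs) {
  w <- length(x)
  mx <- sum(x) / w
  m2 <- sum((x - mx)^2) / w
  m3 <- sum((x - mx)^3) / w
  m4 <- sum((x - mx)^4) / w
  sorted <- sort(x)
  q <- function(p) {  # type-7 quantile by hand
    h <- (w - 1) * p
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    sorted[lo] + (h - floor(h)) * (sorted[hi] - sorted[lo])
  }
  # DFT of mean-removed window by literal summation
  xc <- x - mx
  nf2 <- w %/% 2
  P <- numeric(nf2)
  for (j in seq_len(nf2)) {
    re <- 0; im <- 0
    for (t in 0:(w - 1)) {
      ang <- -2 * pi * j * t / w
      re <- re + xc[t + 1] * cos(ang)
      im <- im + xc[t + 1] * sin(ang)
    }
    P[j] <- re^2 + im^2
  }
  fr <- (seq_len(nf2)) * fs / w
  tot <- sum(P)
  ctr <- sum(fr * P) / tot
  cum <- cumsum(P)
  medf <- fr[which(cum >= tot / 2)[1]]
  pnorm <- P / tot
  pnz <- pnorm[pnorm > 0]
  # zero crossings: sign products, zeros carrying the previous sign
  s <- sign(x)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  zc <- sum(s[-1] != s[-w] & s[-1] != 0 & s[-w] != 0)
  tt <- 0:(w - 1)
  hb <- findInterval(x, seq(min(x), max(x), length.out = 11),
                     rightmost.closed = TRUE)
  hp <- tabulate(hb, nbins = 10) / w
  hp <- hp[hp > 0]
  c(mean = mx,
    std = sqrt(m2),
    var = m2,
    median = q(0.5),
    min = sorted[1],
    max = sorted[w],
    peak_to_peak = sorted[w] - sorted[1],
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2,
    iqr = q(0.75) - q(0.25),
    rms = sqrt(sum(x^2) / w),
    abs_energy = sum(x^2),
    mean_abs_diff = sum(abs(x[-1] - x[-w])) / (w - 1),
    zero_cross = zc,
    slope = sum((tt - mean(tt)) * (x - mx)) / sum((tt - mean(tt))^2),
    autocorr_lag1 = sum((x[-w] - mx) * (x[-1] - mx)) / sum((x - mx)^2),
    hist_entropy = -sum(hp * log(hp)),
    spectral_centroid = ctr,
    spectral_spread = sqrt(sum((fr - ctr)^2 * P) / tot),
    median_freq = medf,
    max_power_freq = fr[which.max(P)],
    spectral_entropy = -sum(pnz * log(pnz)) / log(nf2))
}

# maximum-cardinality tolerance matching by exhaustive recursion (<= 6 a side)
oracle_max_matching <- function(truth, detected, tol) {
  best <- 0
  recurse <- function(ti, used) {
    if (ti > length(truth)) {
      best <<- max(best, sum(used))
      return()
    }
    recurse(ti + 1, used)                       # leave this truth unmatched
    for (di in seq_along(detected)) {
      if (!used[di] && abs(detected[di] - truth[ti]) <= tol) {
        used[di] <- TRUE
        recurse(ti + 1, used)
        used[di] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, length(detected)))
  best
}

# circular autocorrelation at a lag, literal definition
circ_autocor <- function(x, lag) {
  n <- length(x)
  idx <- ((seq_len(n) - 1 + lag) %% n) + 1
  sum(x * x[idx])
}

# canonical relabelling: partitions equal up to label permutation
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# bare curve object for picker unit tests
toy_curve <- function(values) {
  m <- length(values)
  structure(list(values = values, raw = values,
                 window_starts = seq_len(m) - 1L,
                 config = windowing_config(2, 0), fs = 1,
                 n_samples = m + 1L),
            class = c("novelty_curve", "ssm_curve"))
}

random_ssm <- function(m, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(m * m, -1, 1), m, m)
  S <- (A + t(A)) / 2
  diag(S) <- 1
  structure(list(values = S, window_starts = seq_len(m) - 1L,
                 config = windowing_config(2, 0), fs = 1,
                 n_samples = m + 1L),
            class = "ssm_matrix")
}
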