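test_that("sliding windows tile the signal as documented", {
  cfg <- windowing_config(4, 0.5)
  expect_identical(cfg$hop, 2L)
  expect_identical(sliding_windows(10, cfg), c(0L, 2L, 4L, 6L))

  disjoint <- windowing_config(4, 0)
  expect_identical(disjoint$hop, 4L)
  expect_identical(sliding_windows(12, disjoint), c(0L, 4L, 8L))

  expect_identical(sliding_windows(4, disjoint), 0L)  # n == w
  expect_error(sliding_windows(3, disjoint), "shorter than window")
  expect_error(windowing_config(1), "w")
  expect_error(windowing_config(10, 1), "overlap")

  # dense overlap never produces hop 0
  expect_identical(windowing_config(10, 0.95)$hop, 1L)
})

test_that("frame/sample mapping is the window centre and monotone", {
  rec <- ts_record(stats::rnorm(100), fs = 10)
  fm <- extract_features(rec, windowing_config(10, 0.5), feature_set = "mean")
  ctr <- frame_to_sample(fm)
  expect_identical(ctr, fm$window_starts + 5L)
  expect_true(all(diff(ctr) > 0))
  expect_identical(sample_to_frame(fm, ctr), seq_along(ctr) - 1L)
})

test_that("feature rows follow channel-major registry order and handle constants", {
  k <- 3
  rec <- ts_record(matrix(2.5, nrow = 40, ncol = k), fs = 10)
  expect_warning(fm <- extract_features(rec, windowing_config(10, 0)),
                 "non-finite")
  r <- length(feature_names())
  expect_equal(nrow(fm$values), r * k)
  expect_identical(fm$feature_names[1:r], paste0(feature_names(), "_ch0"))
  mean_rows <- which(fm$feature_names %in% paste0("mean_ch", 0:2))
  std_rows <- which(fm$feature_names %in% paste0("std_ch", 0:2))
  expect_true(all(fm$values[mean_rows, ] == 2.5))
  expect_true(all(fm$values[std_rows, ] == 0))

  expect_error(extract_features(rec, windowing_config(10, 0), feature_set = "bogus"),
               "unknown feature")
  expect_error(extract_features(rec, windowing_config(10, 0), feature_set = character(0)),
               "non-empty")
})

test_that("zero-crossing counting matches a full-period sine", {
  # 1 Hz at fs = 100 with a small phase offset (no exact-zero samples):
  # two crossings in any full-period window
  t <- (0:399) / 100
  rec <- ts_record(sin(2 * pi * t + 0.1), fs = 100)
  fm <- extract_features(rec, windowing_config(100, 0), feature_set = "zero_cross")
  expect_true(all(fm$values == 2))
})

test_that("registry values agree with direct-formula oracles on random windows", {
  set.seed(42)
  fs <- 128
  for (i in 1:100) {
    w <- sample(c(16L, 32L, 50L), 1)
    x <- stats::rnorm(w, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.2, 3))
    rec <- ts_record(x, fs = fs)
    fm <- extract_features(rec, windowing_config(w, 0))
    expect_equal(unname(fm$values[, 1]), unname(oracle_features(x, fs)),
                 tolerance = 1e-9)
  }
})

test_that("double normalization z-scores rows then unit-norms columns", {
  rec <- ts_record(stats::rnorm(200, sd = 2), fs = 50)
  fm <- extract_features(rec, windowing_config(20, 0.5))
  nfm <- normalize_fm(fm)
  expect_true(nfm$normalized)
  norms <- sqrt(colSums(nfm$values^2))
  expect_true(all(abs(norms - 1) < 1e-12 | norms == 0))
  expect_error(normalize_fm(nfm), "already normalized")

  # z-score arithmetic with the population standard deviation
  x <- c(1, 2, 3)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # zero-variance rows vanish instead of polluting the cosine
  const_rec <- ts_record(cbind(stats::rnorm(100), 5), fs = 10)
  fm2 <- extract_features(const_rec, windowing_config(10, 0),
                          feature_set = c("mean", "std"))
  expect_warning(nfm2 <- normalize_fm(fm2), "zero-variance")
  expect_true(all(nfm2$values[3:4, ] == 0))
})

test_that("extraction is deterministic given identical inputs", {
  rec <- make_piecewise_signal(list(regime_spec(120), regime_spec(120, mean = 2)),
                               fs = 100, seed = 5)
  a <- extract_features(rec, windowing_config(30, 0.5))
  b <- extract_features(rec, windowing_config(30, 0.5))
  expect_identical(a$values, b$values)
  expect_identical(a$window_starts, b$window_starts)
})
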