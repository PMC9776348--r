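test_that("kernel algebra: sign grid, zero sum, symmetry, zero centre", {
  k1 <- build_kernel(1, 1, normalize = FALSE)
  # pre-taper sign structure survives at the corners (phi > 0 everywhere)
  expect_identical(sign(k1$values),
                   matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3))

  for (L in 1:10) for (sigma in c(0.1, 0.5, 1)) {
    k <- build_kernel(L, sigma, normalize = FALSE)
    expect_lt(abs(sum(k$values)), 1e-12)
    expect_identical(k$values, t(k$values))
    expect_true(all(k$values[L + 1, ] == 0))
    expect_true(all(k$values[, L + 1] == 0))
    expect_identical(k$D, 2L * L + 1L)
  }

  kn <- build_kernel(3, 0.5)
  expect_equal(sum(abs(kn$values)), 1, tolerance = 1e-12)

  expect_error(build_kernel(0, 0.5), "L")
  expect_error(build_kernel(2, 0), "sigma")
})

test_that("tapered kernel equals the elementwise sign-times-Gaussian oracle", {
  k <- build_kernel(8, 0.5, normalize = FALSE)
  expect_equal(k$values, oracle_kernel(8, 0.5), tolerance = 1e-12)
  k2 <- build_kernel(4, 1.5, normalize = FALSE)
  expect_equal(k2$values, oracle_kernel(4, 1.5), tolerance = 1e-12)
})

test_that("novelty of a constant similarity field is identically zero", {
  S <- random_ssm(50, 1)
  S$values <- matrix(1, 50, 50)
  nf <- novelty_function(S, build_kernel(5, 0.5))
  expect_true(all(nf$raw == 0))
  expect_true(all(nf$values == 0))   # flat raw curve maps to zeros
})

test_that("ideal two-block SSM peaks at the block boundary with first-index ties", {
  S <- random_ssm(50, 1)
  block <- matrix(0, 50, 50)
  block[1:25, 1:25] <- 1
  block[26:50, 26:50] <- 1
  S$values <- block
  nf <- novelty_function(S, build_kernel(5, 0.5))
  expect_true((which.max(nf$raw) - 1L) %in% c(24L, 25L))
  expect_identical(which.max(nf$raw) - 1L, 24L)
})

test_that("novelty curve equals the nested-loop correlation oracle", {
  S <- random_ssm(40, 7)
  k <- build_kernel(4, 0.5)
  nf <- novelty_function(S, k)
  expect_equal(nf$raw, oracle_novelty(S$values, k$values, 4L), tolerance = 1e-10)

  expect_error(novelty_function(random_ssm(10, 1), build_kernel(6, 0.5)),
               "exceeds")
})

test_that("normalized novelty is invariant to positive rescaling of the SSM", {
  S <- random_ssm(40, 2)
  k <- build_kernel(4, 0.5)
  a <- novelty_function(S, k)
  S$values <- S$values * 0.25
  b <- novelty_function(S, k)
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("shifting a regime boundary shifts the novelty argmax with it", {
  base_argmax <- function(n1) {
    rec <- make_piecewise_signal(list(regime_spec(n1), regime_spec(1200 - n1, mean = 5)),
                                 fs = 100, channels = 3, seed = 4)
    fm <- suppressWarnings(normalize_fm(extract_features(rec, windowing_config(50, 0.9))))
    S <- compute_ssm(fm)
    nf <- novelty_function(S, build_kernel(10, 0.5))
    which.max(nf$raw) - 1L
  }
  hop <- windowing_config(50, 0.9)$hop
  delta_frames <- 20L
  a <- base_argmax(600L)
  b <- base_argmax(600L + delta_frames * hop)
  expect_lte(abs((b - a) - delta_frames), 1L)
})

test_that("peak picking applies strategies then non-maximum suppression", {
  cv <- toy_curve(c(0, 1, 0, 0.5, 0))
  expect_identical(pick_peaks(cv, "threshold", theta = 0.6)$frame_indices, 1L)
  expect_identical(pick_peaks(cv, "top_n", n = 2)$frame_indices, c(1L, 3L))
  expect_identical(pick_peaks(cv, "peak_fraction", fraction = 0.5)$frame_indices, 1L)

  sup <- toy_curve(c(0, 0.9, 1.0, 0, 0))
  expect_identical(pick_peaks(sup, "threshold", theta = 0.5,
                              min_separation = 2)$frame_indices, 2L)

  # ties resolve to the earlier frame under suppression
  tie <- toy_curve(c(0, 0.8, 0, 0.8, 0))
  expect_identical(pick_peaks(tie, "threshold", theta = 0.5,
                              min_separation = 3)$frame_indices, 1L)

  expect_error(pick_peaks(cv, "threshold", theta = 2), "theta")
  expect_error(pick_peaks(cv, "top_n"), "top_n")
  expect_error(pick_peaks(cv, "peak_fraction", fraction = 0), "fraction")

  # monotone curve has no strict local maxima
  expect_length(pick_peaks(toy_curve(seq(0, 1, 0.1)), "threshold",
                           theta = 0)$frame_indices, 0L)
})
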