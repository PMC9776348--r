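test_that("piecewise generator places boundaries by construction and is reproducible", {
  r <- make_piecewise_signal(list(regime_spec(500), regime_spec(500, mean = 3)),
                             fs = 100, seed = 7)
  expect_equal(nrow(r$samples), 1000L)
  expect_identical(r$events, 500L)

  single <- make_piecewise_signal(list(regime_spec(400)), fs = 100, seed = 7)
  expect_identical(single$events, integer(0))

  again <- make_piecewise_signal(list(regime_spec(500), regime_spec(500, mean = 3)),
                                 fs = 100, seed = 7)
  expect_identical(r$samples, again$samples)
  other <- make_piecewise_signal(list(regime_spec(500), regime_spec(500, mean = 3)),
                                 fs = 100, seed = 8)
  expect_false(identical(r$samples, other$samples))

  multi <- make_piecewise_signal(list(regime_spec(100), regime_spec(100, mean = 1),
                                      regime_spec(100, mean = 2)),
                                 fs = 50, channels = 3, seed = 1)
  expect_equal(dim(multi$samples), c(300L, 3L))
  expect_identical(multi$events, c(100L, 200L))

  expect_error(make_piecewise_signal(list(), fs = 100), "at least one regime")
  expect_error(make_piecewise_signal(list(regime_spec(10)), fs = 0), "fs")
  expect_error(regime_spec(0), "length")
  expect_error(regime_spec(10, std = -1), "std")
})

test_that("sinusoidal regimes carry the requested power", {
  r <- make_piecewise_signal(
    list(regime_spec(300, frequency = 5, amplitude = 1, std = 0.1),
         regime_spec(300, frequency = 1, amplitude = 1, std = 0.1)),
    fs = 100, seed = 3)
  clean <- make_piecewise_signal(
    list(regime_spec(300, frequency = 5, amplitude = 1, std = 0),
         regime_spec(300, frequency = 1, amplitude = 1, std = 0)),
    fs = 100, seed = 3)
  p_sine <- mean(clean$samples[1:300, 1]^2)   # deterministic component, regime 1
  expect_lt(abs(p_sine - 0.5) / 0.5, 0.05)    # amp^2 / 2
  expect_equal(nrow(r$samples), 600L)
})

test_that("periodic generator is exactly periodic with events at period starts", {
  r <- make_periodic_signal(100, 10, "sine", noise_std = 0, fs = 100, seed = 1)
  expect_equal(nrow(r$samples), 1000L)
  expect_identical(r$events, as.integer(seq(100, 900, by = 100)))

  x <- r$samples[, 1]
  expect_lt(abs(circ_autocor(x, 100) - circ_autocor(x, 0)), 1e-9)

  g <- make_periodic_signal(80, 12, "gaussian_pulse", noise_std = 0.05,
                            fs = 100, seed = 11)
  lags <- 1:(nrow(g$samples) %/% 2)
  ac <- vapply(lags, function(l) circ_autocor(g$samples[, 1], l), numeric(1))
  # circular autocorrelation ties exactly at every multiple of the period,
  # so the global argmax must be a multiple of 80 and the fundamental must
  # dominate every off-multiple lag
  expect_identical(lags[which.max(ac)] %% 80L, 0L)
  off <- lags[lags %% 80L != 0L]
  expect_gt(ac[80], max(ac[off]))

  expect_error(make_periodic_signal(3, 5), "period")
  expect_error(make_periodic_signal(100, 1), "n_periods")
})

test_that("noise injection hits the requested SNR and records episode boundaries", {
  clean <- make_periodic_signal(100, 40, "sine", noise_std = 0, fs = 100, seed = 1)
  for (snr in c(6, 12, 24)) {
    noisy <- add_noise_at_snr(clean, snr, c(1000L, 2000L), "white", seed = 2)
    expect_lt(abs(measure_snr(clean, noisy, c(1000L, 2000L)) - snr), 0.2)
  }
  noisy <- add_noise_at_snr(clean, 6, c(1000L, 2000L), "white", seed = 2)
  expect_true(all(c(1000L, 2000L) %in% noisy$events))
  expect_identical(noisy$samples[1:1000, ], clean$samples[1:1000, ])

  passthrough <- add_noise_at_snr(clean, Inf, c(1000L, 2000L), seed = 2)
  expect_identical(passthrough$samples, clean$samples)
  expect_identical(passthrough$events, clean$events)

  for (kind in c("lowfreq_wander", "burst")) {
    nz <- add_noise_at_snr(clean, 12, c(500L, 1500L), kind, seed = 5)
    expect_lt(abs(measure_snr(clean, nz, c(500L, 1500L)) - 12), 0.2)
  }
  expect_error(add_noise_at_snr(clean, 6, c(200L, 200L)), "interval")
})

test_that("record construction enforces its invariants", {
  expect_error(ts_record(matrix(c(1, NaN), 2, 1), fs = 1), "NaN")
  expect_error(ts_record(matrix(1:4, 2, 2), fs = -1), "fs")
  expect_error(ts_record(1:10, fs = 1, events = c(3L, 3L)), "strictly increasing")
  expect_error(ts_record(1:10, fs = 1, events = 10L), "\\[0, n\\)")
  r <- ts_record(cbind(1:5, 6:10), fs = 2)
  expect_identical(r$channel_names, c("ch0", "ch1"))
})
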