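test_that("events split the frame axis into half-open segments", {
  segs <- segments_from_events(c(25L), 50L)
  expect_length(segs, 2L)
  expect_identical(segs[[1]]$start_frame, 0L)
  expect_identical(segs[[1]]$end_frame, 25L)
  expect_identical(segs[[2]]$end_frame, 50L)

  expect_length(segments_from_events(integer(0), 50L), 1L)
  segs4 <- segments_from_events(c(10L, 20L, 30L), 40L)
  expect_length(segs4, 4L)
  expect_true(all(vapply(segs4, function(s) s$end_frame - s$start_frame, integer(1)) == 10L))

  expect_error(segments_from_events(c(5L, 5L), 40L), "duplicate")
})

test_that("similarity profiles are segment-row column means", {
  S <- random_ssm(30, 11)
  seg <- segments_from_events(integer(0), 30L)[[1]]
  seg$start_frame <- 3L; seg$end_frame <- 8L
  p <- similarity_profile(S, seg)
  expect_equal(p$values, oracle_profile(S$values, 4:8), tolerance = 1e-12)

  # single-row segment reproduces the SSM row
  seg1 <- seg; seg1$start_frame <- 4L; seg1$end_frame <- 5L
  expect_equal(similarity_profile(S, seg1)$values, S$values[5, ], tolerance = 1e-15)

  ones <- random_ssm(10, 1)
  ones$values <- matrix(1, 10, 10)
  expect_true(all(similarity_profile(ones, segments_from_events(c(4L), 10L)[[1]])$values == 1))

  bad <- seg; bad$start_frame <- 5L; bad$end_frame <- 5L
  expect_error(similarity_profile(S, bad), "non-empty")
})

test_that("adjacent segment profiles combine by length-weighted average", {
  S <- random_ssm(40, 13)
  segs <- segments_from_events(c(12L), 40L)
  pa <- similarity_profile(S, segs[[1]])
  pb <- similarity_profile(S, segs[[2]])
  whole <- similarity_profile(S, segments_from_events(integer(0), 40L)[[1]])
  la <- 12; lb <- 28
  expect_equal(whole$values, (la * pa$values + lb * pb$values) / (la + lb),
               tolerance = 1e-12)
})

test_that("clustering groups identical profiles and honours k", {
  S <- random_ssm(24, 2)
  segs <- segments_from_events(c(8L, 16L), 24L)
  profs <- lapply(segs, function(s) similarity_profile(S, s))
  profs[[3]] <- profs[[1]]   # force two identical profiles
  cl <- cluster_segments(profs, k = 2)
  expect_identical(cl$labels[1], cl$labels[3])
  expect_false(cl$labels[1] == cl$labels[2])
  expect_identical(as.matrix(cl$distances)[1, 3], 0)

  expect_identical(cluster_segments(profs, k = 1)$labels, rep(1L, 3))
  expect_error(cluster_segments(profs, k = 4), "exceeds")
  expect_error(cluster_segments(profs[1], k = 1), "at least 2")
  expect_error(cluster_segments(profs), "exactly one")

  cut_cl <- cluster_segments(profs, distance_cut = 1e-9)
  expect_identical(cut_cl$labels[1], cut_cl$labels[3])
})

test_that("alternating-regime fixtures recover the true grouping", {
  aba <- function(seed) make_piecewise_signal(
    list(regime_spec(600), regime_spec(600, mean = 4), regime_spec(600)),
    fs = 100, channels = 3, seed = seed)
  for (seed in 1:3) {
    rec <- aba(seed)
    fm <- suppressWarnings(normalize_fm(extract_features(rec, windowing_config(50, 0.95))))
    S <- compute_ssm(fm)
    segs <- segments_from_events(sample_to_frame(S, rec$events), ncol(S$values))
    profs <- lapply(segs, function(s) similarity_profile(S, s))
    cl <- cluster_segments(profs, k = 2)
    expect_true(same_partition(cl$labels, c(1L, 2L, 1L)))
  }
})

test_that("merge trees serialize with heights and labels", {
  S <- random_ssm(24, 2)
  segs <- segments_from_events(c(8L, 16L), 24L)
  profs <- lapply(segs, function(s) similarity_profile(S, s))
  cl <- cluster_segments(profs, k = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_merge_tree(cl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_length(back$height, 2L)
  expect_identical(as.integer(back$labels), cl$labels)
  expect_identical(back$segments$start_frame, c(0L, 8L, 16L))
})
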