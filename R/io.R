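#' Readers, writers and the end-to-end pipeline
#'
#' Delimited-text IO for signals, curves and events, a serializable run
#' configuration, and [run_pipeline()] tying the stages together:
#' features -> SSM -> novelty (and/or periodic) -> profiles
#' (-> evaluation when ground truth is available). All indices written to
#' disk are 0-based sample indices; times in seconds are `sample / fs`.
#'
#' @name cli_io
NULL

#' Read a delimited multichannel time series
#'
#' Accepts CSV with an optional header and an optional leading time
#' column (detected by a name in `time`/`t`/`timestamp`, case-insensitive,
#' combined with monotone increase; it is dropped from the channels, with
#' a warning when its implied rate disagrees with `fs`).
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @param channels Optional channel selection (names or 1-based indices
#'   after time-column removal).
#' @param events Optional integer vector of ground-truth sample indices
#'   to attach.
#' @return A [ts_record()].
#' @export
read_timeseries <- function(path, fs, channels = NULL, events = integer(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) stop("empty file: ", path)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells))))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character", strip.white = TRUE)
  if (!nrow(df)) stop("empty file: ", path)
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, colnames(df)))
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stop(sprintf("non-numeric cell(s) at data row %d of %s", bad[1], path))
  time_col <- which(tolower(colnames(num)) %in% c("time", "t", "timestamp"))
  if (length(time_col) == 1L && nrow(num) > 1L) {
    tv <- num[, time_col]
    if (all(diff(tv) > 0)) {
      implied <- 1 / stats::median(diff(tv))
      if (abs(implied - fs) / fs > 0.01)
        warning(sprintf("time column implies %.4g Hz but fs = %g Hz", implied, fs))
      num <- num[, -time_col, drop = FALSE]
    }
  }
  nm <- colnames(num)
  if (!has_header || is.null(nm) || !any(nzchar(nm)))
    nm <- paste0("ch", seq_len(ncol(num)) - 1L)
  if (!is.null(channels)) {
    sel <- if (is.character(channels)) match(channels, nm) else as.integer(channels)
    if (any(is.na(sel)) || any(sel < 1L | sel > ncol(num)))
      stop("unknown channel selection")
    num <- num[, sel, drop = FALSE]
    nm <- nm[sel]
  }
  ts_record(num, fs = fs, channel_names = nm, events = events)
}

#' Write a time series / events to CSV
#'
#' `write_timeseries` writes one column per channel with a header (and an
#' optional `time` column); `write_events` writes an event list with
#' columns `frame`, `sample`, `time_s`, `score`, `type` (or a bare
#' `sample` column for plain ground-truth vectors); `read_events` reads
#' either form back as sorted sample indices.
#'
#' @param record A [ts_record()].
#' @param path Output path.
#' @param time_column Prepend a `time` seconds column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(record, path, time_column = FALSE) {
  stopifnot(inherits(record, "ts_record"))
  df <- as.data.frame(record$samples)
  names(df) <- record$channel_names
  if (time_column)
    df <- cbind(time = (seq_len(nrow(df)) - 1L) / record$fs, df)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param events An `event_set`, or an integer vector of sample indices.
#' @export
write_events <- function(events, path) {
  df <- if (inherits(events, "event_set")) as.data.frame(events)
        else data.frame(sample = as.integer(events))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!"sample" %in% names(df)) stop("events file lacks a 'sample' column")
  sort(as.integer(df$sample))
}

#' Write an SSM curve (novelty or similarity) to CSV
#'
#' Columns: 0-based `frame`, `sample` (window centre), normalized
#' `value`, and `raw`.
#'
#' @param curve A `novelty_curve` or `similarity_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  frames <- seq_along(curve$values) - 1L
  df <- data.frame(frame = frames, sample = frame_to_sample(curve, frames),
                   value = curve$values, raw = curve$raw)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline run configuration
#'
#' Defaults: `overlap_frac` 0.95 (full-detail SSM at moderate cost);
#' kernel `L` scaled to the frame count (`D ~ 0.2 m`, i.e. `L =
#' round(0.1 * m)`, bounded to `[2, 50]`) when not given; `sigma` 0.5;
#' threshold strategy with `theta` 0.3; `min_separation = L` frames (the
#' kernel half-size governs novelty-peak width); evaluation tolerance `w`
#' samples.
#'
#' @param input Input signal CSV (or `NULL` when a record is passed to
#'   [run_pipeline()] directly).
#' @param fs Sampling rate in Hz (required).
#' @param w Window size in samples (required).
#' @param overlap_frac Window overlap fraction in `[0, 1)`.
#' @param channels Optional channel selection.
#' @param kernel_L Kernel half-size (`NULL` = scale to frame count).
#' @param sigma Kernel taper.
#' @param strategy,theta,top_n,peak_fraction Peak-picking strategy and its
#'   parameter.
#' @param min_separation Minimum peak separation, frames (`NULL` = kernel
#'   half-size).
#' @param detect `"novelty"`, `"periodic"` or both.
#' @param n_clusters Optional cluster count for segment profiles
#'   (`NULL` = skip clustering; requires >= 2 segments).
#' @param linkage Clustering linkage.
#' @param tolerance Evaluation tolerance, samples (`NULL` = `w`).
#' @param seed Integer seed recorded with the run.
#' @param out_dir Output directory for artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, fs, w, overlap_frac = 0.95,
                       channels = NULL, kernel_L = NULL, sigma = 0.5,
                       strategy = "threshold", theta = 0.3, top_n = NULL,
                       peak_fraction = NULL, min_separation = NULL,
                       detect = "novelty", n_clusters = NULL,
                       linkage = "average", tolerance = NULL,
                       seed = 0L, out_dir = NULL) {
  if (missing(fs) || is.null(fs)) stop("config requires fs")
  if (missing(w) || is.null(w)) stop("config requires w")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  cfg <- list(input = input, fs = fs, w = as.integer(w),
              overlap_frac = overlap_frac, channels = channels,
              kernel_L = if (!is.null(kernel_L)) as.integer(kernel_L),
              sigma = sigma, strategy = strategy, theta = theta,
              top_n = top_n, peak_fraction = peak_fraction,
              min_separation = min_separation,
              detect = match.arg(detect, c("novelty", "periodic", "both")),
              n_clusters = n_clusters, linkage = linkage,
              tolerance = tolerance, seed = as.integer(seed),
              out_dir = out_dir)
  windowing_config(cfg$w, cfg$overlap_frac)        # validates w/overlap
  if (!is.null(cfg$kernel_L) && cfg$kernel_L < 1L) stop("kernel_L must be >= 1")
  if (!is.finite(cfg$sigma) || cfg$sigma <= 0) stop("sigma must be > 0")
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration (JSON round-trip)
#'
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   restored `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Run the full SSM segmentation pipeline
#'
#' Stages, in order: feature extraction, double normalization, SSM,
#' novelty and/or periodic detection, segment profiles (+ clustering when
#' `n_clusters` is set), and tolerance-zone evaluation when ground truth
#' is present. When `config$out_dir` is set, every artifact (effective
#' config, FM/SSM CSVs with metadata, curves, events, labels, eval JSON)
#' is written there; outputs are a pure function of config + input +
#' seed. A stage failure aborts with the failing stage named.
#'
#' @param config A `run_config`.
#' @param record Optional [ts_record()]; when `NULL`, `config$input` is
#'   read with [read_timeseries()].
#' @return List with `fm`, `ssm`, `novelty` (`curve`, `events`),
#'   `periodic` (`curve`, `events`) as requested, `segments`,
#'   `clustering` (or `NULL`), `evaluation` (or `NULL`), and the
#'   effective `config`.
#' @export
run_pipeline <- function(config, record = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(record)) {
    if (is.null(config$input)) stop("config has no input and no record was given")
    record <- stage("read", read_timeseries(config$input, config$fs, config$channels))
  }
  wc <- windowing_config(config$w, config$overlap_frac)
  fm <- stage("features", normalize_fm(extract_features(record, wc)))
  S <- stage("ssm", compute_ssm(fm))
  m <- ncol(S$values)
  L <- config$kernel_L
  if (is.null(L)) L <- min(50L, max(2L, as.integer(round(0.1 * m))))
  min_sep <- config$min_separation
  if (is.null(min_sep)) min_sep <- L
  pick <- function(curve, picker) {
    picker(curve, strategy = config$strategy, theta = config$theta,
           n = config$top_n, fraction = config$peak_fraction,
           min_separation = min_sep)
  }
  res <- list(record = record, fm = fm, ssm = S, config = config)
  if (config$detect %in% c("novelty", "both")) {
    kern <- stage("novelty", build_kernel(L, config$sigma))
    nf <- stage("novelty", novelty_function(S, kern))
    res$novelty <- list(curve = nf, events = stage("novelty", pick(nf, pick_peaks)))
  }
  if (config$detect %in% c("periodic", "both")) {
    sf <- stage("periodic", similarity_function(S))
    res$periodic <- list(curve = sf, events = stage("periodic", pick(sf, pick_valleys)))
  }
  seg_events <- if (!is.null(res$novelty)) res$novelty$events else res$periodic$events
  res$segments <- stage("profiles", segments_from_events(seg_events, m))
  if (!is.null(config$n_clusters) && length(res$segments) >= 2L) {
    profs <- stage("profiles",
                   lapply(res$segments, function(s) similarity_profile(S, s)))
    res$clustering <- stage("profiles",
      cluster_segments(profs, linkage = config$linkage, k = config$n_clusters))
  }
  if (length(record$events)) {
    tol <- config$tolerance
    if (is.null(tol)) tol <- config$w
    res$evaluation <- stage("evaluation",
      evaluate_events(record$events, seg_events, tolerance = tol))
  }
  if (!is.null(config$out_dir)) stage("write", write_artifacts(res, config))
  res
}

write_artifacts <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  save_config(config, p("config.json"))
  fmv <- res$fm$values
  utils::write.table(format(fmv, digits = 17, trim = TRUE), p("fm.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(w = res$fm$config$w, hop = res$fm$config$hop,
                            fs = res$fm$fs, feature_names = res$fm$feature_names,
                            window_starts = res$fm$window_starts),
                       p("fm.csv.meta.json"), auto_unbox = TRUE, digits = NA)
  save_ssm(res$ssm, p("ssm.csv"))
  if (!is.null(res$novelty)) {
    write_curve(res$novelty$curve, p("nf.csv"))
    write_events(res$novelty$events, p("novelty_events.csv"))
  }
  if (!is.null(res$periodic)) {
    write_curve(res$periodic$curve, p("sf.csv"))
    write_events(res$periodic$events, p("periodic_events.csv"))
  }
  if (!is.null(res$clustering)) {
    labs <- data.frame(
      start_frame = vapply(res$segments, `[[`, integer(1), "start_frame"),
      end_frame = vapply(res$segments, `[[`, integer(1), "end_frame"),
      label = res$clustering$labels)
    utils::write.csv(labs, p("labels.csv"), row.names = FALSE, quote = FALSE)
    write_merge_tree(res$clustering, p("tree.json"))
  }
  if (!is.null(res$evaluation)) {
    ev <- res$evaluation
    jsonlite::write_json(list(TP = ev$TP, FP = ev$FP, FN = ev$FN,
                              precision = ev$precision, recall = ev$recall,
                              f1 = ev$f1, tolerance = ev$tolerance,
                              pairs = ev$pairs),
                         p("eval.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(config$out_dir)
}

#' Plot an SSM with aligned detection curves
#'
#' Heat map of the SSM with the novelty and/or similarity curve drawn
#' underneath, detected events as vertical lines and ground truth (if
#' any) as triangles. Purely illustrative; no analysis depends on it.
#'
#' @param res A [run_pipeline()] result (or an `ssm_matrix`).
#' @param path Optional PNG path; when given the plot is written there.
#' @return `NULL`, invisibly.
#' @export
plot_ssm <- function(res, path = NULL) {
  S <- if (inherits(res, "ssm_matrix")) res else res$ssm
  curve <- if (!inherits(res, "ssm_matrix") && !is.null(res$novelty))
    res$novelty$curve
  else if (!inherits(res, "ssm_matrix") && !is.null(res$periodic))
    res$periodic$curve
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = if (is.null(curve)) 700 else 900)
    on.exit(grDevices::dev.off())
  }
  if (!is.null(curve)) {
    graphics::layout(matrix(1:2, 2, 1), heights = c(3.5, 1.5))
    op <- graphics::par(mar = c(1, 4, 2, 2))
    on.exit(graphics::par(op), add = TRUE)
  }
  m <- ncol(S$values)
  graphics::image(x = 0:(m - 1), y = 0:(m - 1), z = S$values[, m:1],
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "", ylab = "frame", main = "self-similarity matrix",
                  useRaster = TRUE)
  if (!is.null(curve)) {
    graphics::par(mar = c(4, 4, 1, 2))
    graphics::plot(seq_len(m) - 1L, curve$values, type = "l",
                   xlab = "frame", ylab = class(curve)[1])
    ev <- if (!is.null(res$novelty)) res$novelty$events else res$periodic$events
    graphics::abline(v = ev$frame_indices, col = "red", lty = 2)
  }
  invisible(NULL)
}
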