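#' Feature-based self-similarity matrix
#'
#' The SSM is the Gram matrix of the doubly normalized feature matrix:
#' `SSM = t(FM) %*% FM`. Since columns have unit norm, entry (i, j) is the
#' cosine similarity between frames i and j. Square homogeneous blocks
#' along the diagonal correspond to constant behaviour in the signal;
#' diagonal paths off the main diagonal correspond to recurring patterns.
#'
#' @name ssm
NULL

new_ssm <- function(values, frame_meta) {
  structure(list(values = values,
                 window_starts = frame_meta$window_starts,
                 config = frame_meta$config,
                 fs = frame_meta$fs,
                 n_samples = frame_meta$n_samples),
            class = "ssm_matrix")
}

#' Compute the self-similarity matrix
#'
#' @param fm A normalized `feature_matrix` (see [normalize_fm()]).
#' @return An `ssm_matrix`: `values` is the m x m cosine-similarity matrix,
#'   with the windowing metadata (`window_starts`, `config`, `fs`,
#'   `n_samples`) carried forward so events can be mapped back to samples.
#'   Symmetry and the `[-1, 1]` range are asserted; frames whose feature
#'   column is all zero yield zero rows/columns (similarity 0 to
#'   everything, including themselves).
#' @export
#' @examples
#' rec <- make_piecewise_signal(list(regime_spec(200), regime_spec(200, mean = 4)),
#'                              fs = 100, seed = 1)
#' fm <- normalize_fm(extract_features(rec, windowing_config(50, 0.5)))
#' S <- compute_ssm(fm)
compute_ssm <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!isTRUE(fm$normalized))
    stop("feature matrix must be normalized before computing the SSM")
  v <- crossprod(fm$values)          # t(FM) %*% FM
  v <- (v + t(v)) / 2                # exact symmetry against rounding
  validate_ssm_values(v)
  new_ssm(unname(v), fm)
}

validate_ssm_values <- function(v, tol = 1e-9) {
  if (max(abs(v - t(v))) > tol) stop("SSM is not symmetric")
  if (min(v) < -1 - tol || max(v) > 1 + tol)
    stop("SSM entries outside [-1, 1]")
  invisible(v)
}

#' @export
print.ssm_matrix <- function(x, ...) {
  cat(sprintf("<ssm_matrix> %d x %d frames; w=%d hop=%d fs=%g\n",
              nrow(x$values), ncol(x$values), x$config$w, x$config$hop, x$fs))
  invisible(x)
}

#' @export
dim.ssm_matrix <- function(x) dim(x$values)

#' Persist / restore a self-similarity matrix
#'
#' The matrix is written as dense CSV (full precision) next to a JSON
#' metadata sidecar (`<path>.meta.json`) holding `m`, `w`, `hop`,
#' `overlap_frac`, `fs`, `n_samples` and `window_starts`. Loading
#' validates the declared dimension against the matrix and errors naming
#' any missing metadata field.
#'
#' @param ssm An `ssm_matrix`.
#' @param path CSV file path; the sidecar is written at `<path>.meta.json`.
#' @return `save_ssm` returns `path` invisibly; `load_ssm` returns the
#'   restored `ssm_matrix`.
#' @export
save_ssm <- function(ssm, path) {
  stopifnot(inherits(ssm, "ssm_matrix"))
  utils::write.table(format(ssm$values, digits = 17, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(m = ncol(ssm$values), w = ssm$config$w, hop = ssm$config$hop,
               overlap_frac = ssm$config$overlap_frac, fs = ssm$fs,
               n_samples = ssm$n_samples, window_starts = ssm$window_starts)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ssm
#' @export
load_ssm <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("m", "w", "hop", "overlap_frac", "fs", "n_samples", "window_starts"))
    if (is.null(meta[[field]]))
      stop("metadata sidecar missing field: ", field)
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  if (nrow(v) != meta$m || ncol(v) != meta$m)
    stop(sprintf("matrix is %d x %d but metadata declares m = %d",
                 nrow(v), ncol(v), meta$m))
  validate_ssm_values(v)
  cfg <- windowing_config(meta$w, meta$overlap_frac)
  cfg$hop <- as.integer(meta$hop)
  new_ssm(v, list(window_starts = as.integer(meta$window_starts),
                  config = cfg, fs = meta$fs,
                  n_samples = as.integer(meta$n_samples)))
}
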