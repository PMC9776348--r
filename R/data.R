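#' Published event-detection counts on four biosignal datasets
#'
#' Aggregate TP/FP/FN counts (with the precision/recall/F1 values printed
#' alongside them, to 2 decimals) reported for three unsupervised
#' segmentation approaches — the SSM novelty-function method, window-based
#' segmentation and binary segmentation — on four public biosignal
#' datasets: human activity recognition from waist-worn accelerometry
#' (HAR), ECG noise-episode detection (ECG1), ECG motion-artefact
#' detection at several SNR levels (ECG2), and forearm-EMG gesture
#' on/offset detection (EMG). The counts are inputs for
#' [metrics_from_counts()] and [macro_f1()]; recomputing the metrics from
#' the counts reproduces every printed cell at 2 decimal places.
#'
#' @return Data frame with columns `dataset`, `method`, `TP`, `FP`, `FN`,
#'   `precision_printed`, `recall_printed`, `f1_printed`.
#' @export
#' @examples
#' counts <- benchmark_counts()
#' met <- metrics_from_counts(counts[counts$method == "novelty", ])
#' round(macro_f1(met$f1), 2)  # 0.94
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.csv", package = "ssmseg",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
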