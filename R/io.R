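# Plain-CSV interchange: the dialect used by all pipeline tables is
# comma-separated, header row, empty string for missing values.

#' Write a pipeline table to CSV
#'
#' @param x Data frame (patients, events, telemetry, component scores,
#'   anchors, weekly observations, fits or report tables).
#' @param path Output file path.
#' @export
write_pipeline_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
}

#' Read a pipeline table from CSV
#'
#' @param path File written by [write_pipeline_csv()] (empty string =
#'   missing).
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
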