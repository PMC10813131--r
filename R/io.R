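# Portable recording container: raw little-endian float64 samples plus a JSON
# sidecar carrying fs, channel names and stage annotations.

#' Write / read a recording in the portable array container
#'
#' The container is a pair of files: `<prefix>.dat`, the data matrix as
#' little-endian float64 in channels-fastest (column-major channels x
#' samples) order, and `<prefix>.json`, a sidecar with the sampling rate,
#' channel names, dimensions and stage annotations.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns the [eeg_recording()].
#' @export
write_recording <- function(rec, prefix) {
  if (!inherits(rec, "eeg_recording")) stop_invalid("rec must be an eeg_recording")
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  sidecar <- list(
    format = "plvnet-recording-v1",
    subject_id = rec$subject_id,
    fs = rec$fs,
    channels = rec$channels,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    dtype = "float64", byte_order = "little",
    layout = "channels_x_samples_column_major",
    annotations = rec$annotations
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  jf <- paste0(prefix, ".json"); df <- paste0(prefix, ".dat")
  if (!file.exists(jf) || !file.exists(df))
    stop_invalid("recording container not found at prefix %s", prefix)
  side <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(side$format, "plvnet-recording-v1"))
    stop_invalid("unrecognized container format in %s", jf)
  n <- side$n_channels * side$n_samples
  con <- file(df, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(x) != n) stop_invalid("truncated data file %s", df)
  ann <- as.data.frame(side$annotations)
  eeg_recording(matrix(x, side$n_channels, side$n_samples), side$fs,
                side$channels, ann, side$subject_id)
}

#' Write / read a PLV matrix as channel-labelled TSV
#'
#' @param M A [plv_matrix()] (or plain labelled matrix for `write_matrix_tsv`).
#' @param path TSV path.
#' @return The path (write) or the matrix (read), invisibly for writes.
#' @export
write_matrix_tsv <- function(M, path) {
  vals <- if (inherits(M, "plv_matrix")) M$values else as.matrix(M)
  utils::write.table(vals, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                              check.names = FALSE))
}

#' Write per-subject event logs as CSV
#'
#' @param logs Data frame from [simulate_event_log()] (rows of several
#'   subjects may be concatenated).
#' @param path CSV path.
#' @export
write_event_log <- function(logs, path) {
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}
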