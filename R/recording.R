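#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in samples/s.
#' @param channels Character vector of unique channel names, one per row.
#' @param annotations Data frame with columns `stage, start_s, end_s` marking
#'   stage spans within the signal extent.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, annotations = NULL,
                          subject_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stop_invalid("recording data must be a numeric matrix without NA")
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop_invalid("fs must be > 0")
  channels <- as.character(channels)
  if (length(channels) != nrow(data))
    stop_invalid("got %d channel names for %d data rows",
                 length(channels), nrow(data))
  if (anyDuplicated(channels)) stop_invalid("channel names must be unique")
  rownames(data) <- channels
  n_s <- ncol(data) / fs
  if (is.null(annotations)) {
    annotations <- data.frame(stage = character(), start_s = numeric(),
                              end_s = numeric())
  } else {
    annotations <- as.data.frame(annotations)
    need <- c("stage", "start_s", "end_s")
    if (!all(need %in% names(annotations)))
      stop_invalid("annotations need columns stage, start_s, end_s")
    annotations <- annotations[, need]
    annotations$stage <- as.character(annotations$stage)
    bad <- annotations$start_s < -1e-9 | annotations$end_s > n_s + 1e-9 |
      annotations$start_s >= annotations$end_s
    if (any(bad))
      stop_invalid("annotation span outside signal extent (0-%g s)", n_s)
  }
  structure(list(data = data, fs = fs, channels = channels,
                 annotations = annotations, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (nrow(x$annotations)) {
    spans <- vapply(split(x$annotations, x$annotations$stage), function(a)
      sprintf("%s (%.0f s)", a$stage[1], sum(a$end_s - a$start_s)), "")
    cat("  stages:", paste(spans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fixed-length epoch set
#'
#' Epochs of one subject/stage, optionally band-filtered. The canonical
#' segmentation is 2-s windows, i.e. `round(2 * fs)` samples per epoch.
#'
#' @param x Numeric array `n_epochs x n_channels x samples_per_epoch`.
#' @param fs Sampling rate in samples/s.
#' @param channels Channel names (length = dim 2).
#' @param band A [band_spec()] or the string `"broadband"`.
#' @param stage Stage code the epochs were cut from.
#' @param subject_id Subject identifier.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(x, fs, channels, band = "broadband",
                       stage = NA_character_, subject_id = NA_character_) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop_invalid("epochs must be a 3-d array (epochs x channels x samples)")
  if (anyNA(x)) stop_invalid("epochs contain NA")
  if (dim(x)[1] < 1L) stop_invalid("need at least one epoch")
  if (dim(x)[3] < 2L) stop_invalid("epochs must have at least 2 samples")
  channels <- as.character(channels)
  if (length(channels) != dim(x)[2])
    stop_invalid("got %d channel names for %d channel rows",
                 length(channels), dim(x)[2])
  if (!identical(band, "broadband")) band <- as_band(band)
  structure(list(x = x, fs = as.numeric(fs), channels = channels, band = band,
                 stage = stage, subject_id = subject_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  bn <- if (identical(x$band, "broadband")) "broadband" else x$band$name
  cat(sprintf(
    "<eeg_epochs> %s stage %s [%s]: %d epochs x %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$stage, bn, dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], x$fs))
  invisible(x)
}

n_epochs <- function(e) dim(e$x)[1]
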