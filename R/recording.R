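#' Multichannel EEG recordings
#'
#' The central data container: a channels-by-samples numeric matrix in
#' microvolts with a sampling rate, a [montage], and optional behavioural
#' annotations (intervals labelled e.g. "active"/"inactive").
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param fs sampling rate in Hz.
#' @param montage a [montage] whose channel count matches `nrow(data)`.
#' @param annotations optional data.frame with columns `start_s`, `end_s`,
#'   `label` describing intervals in seconds from recording onset.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, montage, annotations = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop_invalid("a recording needs at least 2 channels")
  if (ncol(data) < 1L) stop_invalid("a recording needs at least 1 sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_invalid("fs must be a positive sampling rate in Hz")
  if (!inherits(montage, "montage"))
    stop_invalid("montage must be a montage object")
  if (length(montage$channel_names) != nrow(data))
    stop_invalid("montage channel count (", length(montage$channel_names),
                 ") does not match data rows (", nrow(data), ")")
  if (!all(is.finite(data)))
    stop_invalid("recording data must be finite")
  rownames(data) <- montage$channel_names
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("start_s", "end_s", "label") %in% names(annotations)))
  }
  structure(list(data = data, fs = fs, montage = montage,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      sep = "")
  if (!is.null(x$annotations))
    cat("  annotations: ", nrow(x$annotations), " intervals\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

# Slice a recording by sample indices, keeping fs and montage.
slice_recording <- function(rec, idx) {
  recording(rec$data[, idx, drop = FALSE], rec$fs, rec$montage)
}
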