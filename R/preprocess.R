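#' Re-reference a recording to the common average
#'
#' Subtracts each sample's mean across channels, so every topography has
#' zero channel mean. Idempotent.
#'
#' @param rec an [recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  X <- rec$data
  X <- X - rep(colMeans(X), each = nrow(X))
  recording(X, rec$fs, rec$montage, rec$annotations)
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR design with `n_taps` coefficients, applied
#' forward and backward ("two-way") for zero phase distortion. Defaults
#' follow broadband microstate preprocessing: 1-40 Hz with 2000 taps.
#'
#' @param rec an [recording()].
#' @param lo,hi band edges in Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param n_taps number of FIR coefficients (filter order + 1).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, lo = 1, hi = 40, n_taps = 2000L) {
  fs <- rec$fs
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop_invalid("band must satisfy 0 < lo < hi < fs/2 (fs = ", fs, ")")
  if (n_taps < 3L) stop_invalid("n_taps must be >= 3")
  b <- as.numeric(signal::fir1(as.integer(n_taps) - 1L,
                               c(lo, hi) / (fs / 2), type = "pass"))
  X <- rec$data
  Y <- t(apply(X, 1L, function(x) signal::filtfilt(filt = b, a = 1, x = x)))
  recording(Y, fs, rec$montage, rec$annotations)
}

#' Extract behavioural-inactivity segments
#'
#' Keeps annotated intervals whose label matches `label` and whose duration
#' is at least `min_len_s` (default 2 s; shorter epochs are excluded).
#' If nothing qualifies, an empty segment set is returned together with a
#' warning of class `ratstates_empty_segments`.
#'
#' @param rec an [recording()] with annotations.
#' @param min_len_s minimum segment length in seconds.
#' @param label annotation label identifying inactivity.
#' @return An object of class `segment_set`: list of recording slices plus
#'   per-segment provenance (source interval in seconds).
#' @export
segment_inactivity <- function(rec, min_len_s = 2, label = "inactive") {
  if (is.null(rec$annotations))
    stop_invalid("recording has no annotations")
  ann <- rec$annotations
  keep <- ann$label == label & (ann$end_s - ann$start_s) >= min_len_s
  ann <- ann[keep, , drop = FALSE]
  segs <- list(); prov <- list()
  for (i in seq_len(nrow(ann))) {
    i0 <- floor(ann$start_s[i] * rec$fs) + 1L
    i1 <- min(ncol(rec$data), floor(ann$end_s[i] * rec$fs))
    if (i1 < i0) next
    segs[[length(segs) + 1L]] <- slice_recording(rec, i0:i1)
    prov[[length(prov) + 1L]] <- c(start_s = ann$start_s[i],
                                   end_s = ann$end_s[i])
  }
  if (!length(segs))
    warning(structure(class = c("ratstates_empty_segments", "warning",
                                "condition"),
                      list(message = "no inactivity segment of sufficient length",
                           call = sys.call(-1))))
  structure(list(segments = segs, provenance = prov,
                 min_len_s = min_len_s),
            class = "segment_set")
}

#' Concatenate segments into one continuous recording
#'
#' Segments are joined in order with no tapering; the result is treated as
#' one continuous series. All segments must share fs and montage.
#'
#' @param segs a `segment_set` (or plain list of recordings).
#' @return A single [recording()].
#' @export
concatenate_segments <- function(segs) {
  segments <- if (inherits(segs, "segment_set")) segs$segments else segs
  if (!length(segments)) stop_invalid("no segments to concatenate")
  fs <- segments[[1L]]$fs
  mont <- segments[[1L]]$montage
  for (s in segments) {
    if (s$fs != fs) stop_invalid("segments differ in sampling rate")
    if (!identical(s$montage$channel_names, mont$channel_names))
      stop_invalid("segments differ in montage")
  }
  recording(do.call(cbind, lapply(segments, `[[`, "data")), fs, mont)
}
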