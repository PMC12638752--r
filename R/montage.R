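#' Electrode montages
#'
#' A montage is the ordered set of electrode labels together with their
#' positions on the skull, in millimetres, using an anteroposterior (AP) /
#' lateral (L) convention (positive AP = anterior to bregma, positive L =
#' right). The built-in layouts mirror the human 10-20 label set placed
#' homologously on the rat skull: the 21-channel layout is the full implant
#' and the 19-channel layout is the analysis subset used for source work.
#'
#' @param channel_names character vector of unique electrode labels.
#' @param positions numeric matrix, one row per channel, 2 or 3 columns of
#'   millimetre coordinates.
#' @return An object of class `montage`: a list with `channel_names` and
#'   `positions`.
#' @export
montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (length(channel_names) < 2L)
    stop_invalid("a montage needs at least 2 channels")
  if (anyDuplicated(channel_names))
    stop_invalid("channel names must be unique")
  if (nrow(positions) != length(channel_names))
    stop_invalid("positions must have one row per channel")
  if (!all(is.finite(positions)))
    stop_invalid("positions must be finite")
  rownames(positions) <- channel_names
  structure(list(channel_names = channel_names, positions = positions),
            class = "montage")
}

# 10-20 labels with schematic rat-skull coordinates (mm, AP/L relative to
# bregma). The AP extent of the rat cortex is roughly +5 to -9 mm; the
# layout preserves the anterior-posterior / left-right ordering of the
# human system rather than any one atlas table.
.layout_1020 <- function() {
  tab <- rbind(
    Fp1 = c( 4.5, -1.5), Fpz = c( 5.0,  0.0), Fp2 = c( 4.5,  1.5),
    F7  = c( 2.5, -4.0), F3  = c( 2.5, -2.0), Fz  = c( 2.5,  0.0),
    F4  = c( 2.5,  2.0), F8  = c( 2.5,  4.0),
    T3  = c(-1.0, -4.5), C3  = c(-1.0, -2.5), Cz  = c(-1.0,  0.0),
    C4  = c(-1.0,  2.5), T4  = c(-1.0,  4.5),
    T5  = c(-4.5, -4.0), P3  = c(-4.5, -2.0), Pz  = c(-4.5,  0.0),
    P4  = c(-4.5,  2.0), T6  = c(-4.5,  4.0),
    O1  = c(-7.5, -1.5), Oz  = c(-8.0,  0.0), O2  = c(-7.5,  1.5))
  colnames(tab) <- c("ap_mm", "lat_mm")
  tab
}

#' Generate a montage
#'
#' `n_channels = 21` returns the full rat-homologous 10-20 implant layout;
#' `n_channels = 19` drops the midline Fpz/Oz pair, the conventional
#' 19-electrode analysis set. Any other count (>= 2) returns a generic
#' circular layout with synthetic labels.
#'
#' @param n_channels number of electrodes.
#' @return A [montage].
#' @examples
#' m <- generate_montage(19)
#' length(m$channel_names)
#' @export
generate_montage <- function(n_channels = 19L) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels <= 0L)
    stop_invalid("n_channels must be a positive count")
  if (n_channels == 1L)
    stop_invalid("a montage needs at least 2 channels")
  full <- .layout_1020()
  if (n_channels == 21L)
    return(montage(rownames(full), full))
  if (n_channels == 19L) {
    keep <- setdiff(rownames(full), c("Fpz", "Oz"))
    return(montage(keep, full[keep, , drop = FALSE]))
  }
  theta <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  pos <- cbind(ap_mm = 5 * cos(theta), lat_mm = 5 * sin(theta))
  montage(sprintf("E%02d", seq_len(n_channels)), pos)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels: ",
      paste(head(x$channel_names, 8L), collapse = " "),
      if (length(x$channel_names) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}
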