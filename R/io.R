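#' Read and write recordings
#'
#' Two on-disk dialects are supported:
#' * **CSV + JSON sidecar** — samples as rows, channels as columns, header
#'   row of channel names, '.' decimal, UTF-8; the sidecar `<stem>.json`
#'   carries `fs`, channel names, positions and optional annotations.
#' * **EDF** — European Data Format, 16-bit, one-second data records.
#'
#' `write_recording()` picks the dialect from the file extension
#' (`.csv` or `.edf`); `read_recording()` likewise.
#'
#' @param rec an [recording()].
#' @param path output/input path.
#' @return `read_recording()` returns an [recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = .write_csv_recording(rec, path),
    edf = write_edf(rec, path),
    stop_invalid("unsupported extension '", ext, "' (use .csv or .edf)"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = .read_csv_recording(path),
    edf = read_edf(path),
    stop_invalid("unsupported extension '", ext, "' (use .csv or .edf)"))
}

.sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

.write_csv_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$montage$channel_names
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs = rec$fs,
               channel_names = rec$montage$channel_names,
               positions = unname(apply(rec$montage$positions, 1L,
                                        as.numeric, simplify = FALSE)))
  if (!is.null(rec$annotations)) meta$annotations <- rec$annotations
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_csv_recording <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar for ", path, " (expected ", side, ")")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df), as.character(meta$channel_names)))
    stop("channel names in CSV header do not match sidecar")
  pos <- if (is.matrix(meta$positions)) meta$positions
         else do.call(rbind, lapply(meta$positions, as.numeric))
  mont <- montage(meta$channel_names, pos)
  ann <- if (!is.null(meta$annotations)) as.data.frame(meta$annotations)
  recording(t(as.matrix(df)), meta$fs, mont, annotations = ann)
}

# --- Minimal EDF (16-bit, 1-second records) -------------------------------
# Fixed-layout ASCII header + int16 little-endian data records. Only what a
# round trip of a continuous multichannel recording needs; annotations and
# EDF+ extensions are not handled. The true sample count is stamped into the
# free-text recording-id field so padding of the final record is undone on
# read.

.pad <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' @rdname write_recording
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_invalid("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  C <- nrow(rec$data); T <- ncol(rec$data)
  n_rec <- ceiling(T / fs)
  X <- rec$data
  if (n_rec * fs > T)
    X <- cbind(X, matrix(0, C, n_rec * fs - T))
  pmin_ <- apply(X, 1L, min); pmax_ <- apply(X, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(.pad("0", 8L), .pad("synthetic rat EEG", 80L),
                .pad(paste0("ratstates T=", T), 80L),
                .pad("01.01.00", 8L), .pad("00.00.00", 8L),
                .pad(256L * (1L + C), 8L), .pad("", 44L),
                .pad(n_rec, 8L), .pad("1", 8L), .pad(C, 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, n) writeChar(paste0(vapply(vals, .pad, "", n = n),
                                            collapse = ""), con, eos = NULL)
  fld(rec$montage$channel_names, 16L)
  fld(rep("", C), 80L)
  fld(rep("uV", C), 8L)
  fld(formatC(pmin_, digits = 6, format = "g"), 8L)
  fld(formatC(pmax_, digits = 6, format = "g"), 8L)
  fld(rep(dmin, C), 8L)
  fld(rep(dmax, C), 8L)
  fld(rep("", C), 80L)
  fld(rep(fs, C), 8L)
  fld(rep("", C), 32L)
  # re-read the printed physical ranges so scaling is exact on read
  pmin_r <- as.numeric(formatC(pmin_, digits = 6, format = "g"))
  pmax_r <- as.numeric(formatC(pmax_, digits = 6, format = "g"))
  scale_ <- (pmax_r - pmin_r) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(C)) {
      dig <- round((X[ch, cols] - pmin_r[ch]) / scale_[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8L); rd(80L)
  recid <- rd(80L)
  rd(8L); rd(8L)
  rd(8L)  # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  C <- as.integer(rd(4L))
  if (is.na(C) || C < 1L) stop("not a readable EDF header")
  rdv <- function(n) vapply(seq_len(C), function(i) rd(n), "")
  labels <- rdv(16L); rdv(80L); rdv(8L)
  pmin_ <- as.numeric(rdv(8L)); pmax_ <- as.numeric(rdv(8L))
  dmin <- as.numeric(rdv(8L)); dmax <- as.numeric(rdv(8L))
  rdv(80L)
  spr <- as.integer(rdv(8L))
  rdv(32L)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a common sampling rate only")
  fs <- spr[1L] / rec_dur
  X <- matrix(0, C, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(C)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      X[ch, cols] <- pmin_[ch] +
        (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  m <- regmatches(recid, regexec("T=([0-9]+)", recid))[[1L]]
  if (length(m) == 2L) {
    T_true <- as.integer(m[2L])
    if (T_true <= ncol(X)) X <- X[, seq_len(T_true), drop = FALSE]
  }
  mont <- generate_montage(C)
  if (all(labels %in% mont$channel_names) && !anyDuplicated(labels)) {
    mont <- montage(labels, mont$positions[labels, , drop = FALSE])
  } else if (!anyDuplicated(labels)) {
    theta <- 2 * pi * (seq_len(C) - 1L) / C
    mont <- montage(labels, cbind(5 * cos(theta), 5 * sin(theta)))
  }
  recording(X, fs, mont)
}
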