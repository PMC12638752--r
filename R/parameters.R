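# Run-length decomposition of a label sequence. NA (unassigned) samples
# break runs and are excluded. Returns one row per run with its class,
# first/last sample and duration under the halfway-boundary convention:
# a run of L samples spans L/fs seconds (half a sample period is gained on
# each interior side; edge runs are measured from the recording edge to the
# halfway boundary, which gives the same L/fs).
label_runs <- function(labels, fs) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  data.frame(class = r$values[keep], start = starts[keep], end = ends[keep],
             n = r$lengths[keep], duration_s = r$lengths[keep] / fs)
}

#' Classical microstate parameters
#'
#' Per class k:
#' * `gfp_k` — mean GFP over samples assigned to k (µV);
#' * `duration_s` — mean dwell time, using the halfway-boundary convention
#'   (consecutive same-class samples; the dwell begins and ends halfway
#'   between the bounding samples, so an interior run of L samples lasts
#'   L/fs seconds); also reported as `duration_ms`;
#' * `occurrence_per_s` — class onsets per second of assigned time;
#' * `coverage` — fraction of assigned samples in the class.
#'
#' Unassigned (zero-GFP) samples are excluded from all denominators, so
#' coverages sum to 1 and `coverage = occurrence x duration` holds up to
#' discretization.
#'
#' @param labels a `label_sequence` (or integer vector with `NA`s).
#' @param gfp a `gfp_series` (or numeric vector) aligned with the labels.
#' @param fs sampling rate in Hz (taken from `labels` if available).
#' @return A `microstate_stats` data.frame with one row per class `1..K`
#'   and columns `class`, `gfp_k`, `duration_s`, `duration_ms`,
#'   `occurrence_per_s`, `coverage`, `n_runs`, `n_samples`.
#' @export
microstate_parameters <- function(labels, gfp, fs = NULL) {
  k <- NULL
  if (inherits(labels, "label_sequence")) {
    if (is.null(fs)) fs <- labels$fs
    k <- labels$k
    labels <- labels$labels
  }
  if (inherits(gfp, "gfp_series")) gfp <- gfp$values
  if (is.null(fs) || fs <= 0) stop_invalid("fs must be positive")
  if (length(labels) != length(gfp))
    stop_invalid("labels and gfp lengths differ")
  if (all(is.na(labels)))
    stop(structure(class = c("ratstates_undefined_stats", "error",
                             "condition"),
                   list(message = "no assigned samples", call = sys.call(-1))))
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  runs <- label_runs(labels, fs)
  n_assigned <- sum(!is.na(labels))
  total_s <- n_assigned / fs
  out <- do.call(rbind, lapply(seq_len(k), function(cl) {
    rr <- runs[runs$class == cl, , drop = FALSE]
    n_samp <- sum(rr$n)
    data.frame(class = cl,
               gfp_k = if (n_samp) mean(gfp[!is.na(labels) & labels == cl])
                       else NA_real_,
               duration_s = if (nrow(rr)) mean(rr$duration_s) else NA_real_,
               duration_ms = if (nrow(rr)) 1000 * mean(rr$duration_s)
                             else NA_real_,
               occurrence_per_s = nrow(rr) / total_s,
               coverage = n_samp / n_assigned,
               n_runs = nrow(rr), n_samples = n_samp)
  }))
  attr(out, "fs") <- fs
  attr(out, "n_assigned") <- n_assigned
  attr(out, "total_s") <- total_s
  class(out) <- c("microstate_stats", "data.frame")
  out
}

#' Occurrence-based expected transition matrix
#'
#' The expected probability of a transition from class k1 to k2 under
#' independence, given only the class occurrence rates:
#' `ExpTM(k1, k2) = (Occ(k1)/MeanOcc * Occ(k2)/MeanOcc) / (1 - Occ(k1)/MeanOcc)`.
#' The diagonal is set to zero (self-transitions are impossible in a run
#' sequence). If `Occ(k1) = MeanOcc` the stated formula is singular; the
#' affected entries are returned as `+Inf` with a warning rather than
#' silently altered.
#'
#' @param occ numeric vector of occurrence rates per class (1/s).
#' @return K x K matrix of expected transition weights.
#' @export
expected_transitions <- function(occ) {
  K <- length(occ)
  mean_occ <- mean(occ)
  a <- occ / mean_occ
  denom <- 1 - a
  out <- matrix(0, K, K)
  for (i in seq_len(K)) {
    if (occ[i] == 0) next
    if (denom[i] == 0) {
      warning("ExpTM singular: Occ(", i, ") equals the mean occurrence; ",
              "returning +Inf for that row")
      out[i, ] <- ifelse(occ > 0, Inf, 0)
    } else {
      out[i, ] <- a[i] * a / denom[i]
    }
  }
  diag(out) <- 0
  out
}

# Row-normalize so off-diagonal rows sum to 1. Raw expected-transition rows
# are uniformly negative when a class occurs more often than the mean (the
# formula's denominator 1 - Occ/MeanOcc flips sign), so normalizing by the
# row sum restores a proper probability row in that regime too. Rows
# containing +Inf split the mass equally over the Inf entries.
row_normalize <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    if (any(is.infinite(r))) {
      out[i, ] <- ifelse(is.infinite(r), 1 / sum(is.infinite(r)), 0)
    } else {
      s <- sum(r)
      out[i, ] <- if (s != 0) r / s else r
    }
  }
  out
}

#' Observed vs expected microstate transitions
#'
#' Observed transitions are run-to-run class changes (self-transitions are
#' impossible by construction), row-normalized to probabilities. Expected
#' transitions come from [expected_transitions()] on the observed
#' occurrence rates and are row-normalized the same way before the
#' difference is taken.
#'
#' @param labels a `label_sequence` (or integer vector).
#' @param fs sampling rate, needed when `labels` is a bare vector.
#' @param k number of classes (inferred if missing).
#' @return An object of class `transition_analysis`: list with `observed`,
#'   `expected` (raw ExpTM), `expected_norm`, `difference`
#'   (= observed - expected_norm) and `counts`.
#' @export
transition_analysis <- function(labels, fs = NULL, k = NULL) {
  if (inherits(labels, "label_sequence")) {
    if (is.null(fs)) fs <- labels$fs
    if (is.null(k)) k <- labels$k
    labels <- labels$labels
  }
  if (is.null(fs)) fs <- 1
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  runs <- label_runs(labels, fs)
  if (nrow(runs) < 2L)
    stop_invalid("need at least 2 runs for a transition analysis")
  seqc <- runs$class
  from <- seqc[-length(seqc)]; to <- seqc[-1L]
  ok <- from != to      # identical classes across an NA gap are not switches
  counts <- matrix(0, k, k)
  for (i in which(ok)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  observed <- row_normalize(counts)
  occ <- vapply(seq_len(k), function(cl) sum(seqc == cl), 0) /
    (sum(!is.na(labels)) / fs)
  expected <- expected_transitions(occ)
  expected_norm <- row_normalize(expected)
  structure(list(observed = observed, expected = expected,
                 expected_norm = expected_norm,
                 difference = observed - expected_norm,
                 counts = counts, occurrence = occ),
            class = "transition_analysis")
}

#' @export
print.transition_analysis <- function(x, ...) {
  cat("<transition_analysis> K = ", nrow(x$observed), ", ",
      sum(x$counts), " observed switches\n", sep = "")
  invisible(x)
}
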