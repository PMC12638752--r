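#' Global field power
#'
#' GFP at sample t is the population standard deviation of the
#' instantaneous topography across channels (the full channel set is the
#' population, hence the 1/C normalisation, not 1/(C-1)).
#'
#' @param rec an [recording()] (average-referenced; re-referencing is
#'   applied defensively).
#' @return An object of class `gfp_series`: list with `values`
#'   (non-negative, per sample), `peak_indices` (strict interior local
#'   maxima) and `fs`.
#' @export
compute_gfp <- function(rec) {
  X <- rec$data
  if (!all(is.finite(X))) stop_invalid("non-finite samples in recording")
  X <- X - rep(colMeans(X), each = nrow(X))
  v <- sqrt(colMeans(X^2))
  structure(list(values = v, peak_indices = find_gfp_peaks(v), fs = rec$fs),
            class = "gfp_series")
}

#' Find GFP peaks
#'
#' Strict interior local maxima of a non-negative series. On a plateau of
#' tied maximal values the first sample is taken as the peak (deterministic,
#' order-stable). Endpoints are never peaks.
#'
#' @param gfp numeric vector, or a `gfp_series`.
#' @return Integer vector of peak sample indices (possibly empty).
#' @export
find_gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  n <- length(v)
  if (n < 3L) return(integer(0))
  # collapse plateaus: index of the first sample of each run of equal values
  r <- rle(v)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  vals <- r$values
  m <- length(vals)
  if (m < 3L) return(integer(0))
  mid <- 2:(m - 1L)
  is_peak <- vals[mid] > vals[mid - 1L] & vals[mid] > vals[mid + 1L]
  sort(starts[mid][is_peak])
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels; with `ignore_polarity = TRUE`
#' (the default, matching standard microstate practice) the absolute value
#' is returned, treating a map and its negation as identical.
#'
#' @param u,v numeric topographies of equal length (>= 3 channels).
#' @param ignore_polarity take the absolute value?
#' @return Correlation in `[-1, 1]`, or `[0, 1]` when polarity is ignored.
#' @export
spatial_correlation <- function(u, v, ignore_polarity = TRUE) {
  if (length(u) != length(v)) stop_invalid("topographies differ in length")
  if (length(u) < 3L) stop_invalid("need at least 3 channels")
  if (sd(u) == 0 || sd(v) == 0)
    stop(structure(class = c("ratstates_undefined_correlation", "error",
                             "condition"),
                   list(message = "correlation undefined for a constant map",
                        call = sys.call(-1))))
  r <- cor(u, v)
  if (ignore_polarity) abs(r) else r
}
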