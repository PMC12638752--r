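#' Temporally shuffled surrogate recordings
#'
#' For each repeat and each channel independently, a random cut position is
#' drawn and the two resulting blocks are swapped (a circular rotation by a
#' per-channel offset). This destroys the instantaneous cross-channel
#' topography — the structure microstates live on — while preserving each
#' channel's marginal amplitude distribution exactly. A multi-cut variant
#' (`method = "multicut"`) splits each channel at several random positions
#' and permutes the blocks.
#'
#' @param rec an [recording()] with at least 4 samples.
#' @param n_repeats number of surrogates (default 10).
#' @param seed master seed; offsets fan out deterministically per
#'   (repeat, channel).
#' @param method `"rotate"` (one cut, blocks swapped; default) or
#'   `"multicut"`.
#' @param n_cuts number of cuts for `"multicut"` (default 8).
#' @return List of surrogate recordings.
#' @export
shuffle_recording <- function(rec, n_repeats = 10L, seed = 1L,
                              method = c("rotate", "multicut"),
                              n_cuts = 8L) {
  method <- match.arg(method)
  X <- rec$data
  C <- nrow(X); n <- ncol(X)
  if (n < 4L) stop_invalid("need at least 4 samples to shuffle")
  lapply(seq_len(n_repeats), function(r) {
    Y <- with_seed(child_seed(seed, 7L, r), {
      out <- X
      for (ch in seq_len(C)) {
        if (method == "rotate") {
          cut <- sample.int(n - 1L, 1L)
          out[ch, ] <- X[ch, c((cut + 1L):n, 1L:cut)]
        } else {
          cuts <- sort(sample.int(n - 1L, min(n_cuts, n - 1L)))
          bounds <- c(0L, cuts, n)
          blocks <- lapply(seq_len(length(bounds) - 1L), function(b)
            (bounds[b] + 1L):bounds[b + 1L])
          out[ch, ] <- X[ch, unlist(blocks[sample.int(length(blocks))])]
        }
      }
      out
    })
    recording(Y, rec$fs, rec$montage)
  })
}

#' Robust outlier screen by scaled MAD
#'
#' An outlier is a value more than three scaled median absolute deviations
#' from the median, with scaled MAD = 1.4826 x median(|x - median(x)|).
#' If the MAD is zero (no spread) nothing is dropped and a warning is
#' emitted.
#'
#' @param values numeric vector.
#' @return List with `values` (kept), `mask` (logical, `TRUE` = kept) and
#'   `threshold`.
#' @export
mad_outlier_filter <- function(values) {
  if (!length(values)) stop_invalid("empty input")
  med <- median(values)
  smad <- 1.4826 * median(abs(values - med))
  if (smad == 0) {
    warning("scaled MAD is zero; no outliers removed")
    return(list(values = values, mask = rep(TRUE, length(values)),
                threshold = 0))
  }
  mask <- abs(values - med) <= 3 * smad
  list(values = values[mask], mask = mask, threshold = 3 * smad)
}

# totGEV of one recording at K classes: fit on its GFP peaks, evaluate on
# peaks. With refit = FALSE an existing model is backfitted instead.
.rec_totgev <- function(rec, k, model = NULL) {
  if (is.null(model)) {
    fit <- fit_microstates(rec, k_min = k, k_max = k)
    model <- fit$models[[as.character(k)]]
  }
  compute_gev(rec, model)$tot_gev
}

#' Real-vs-surrogate GEV contrast
#'
#' For every recording: fit microstates at K on the GFP peaks and compute
#' totGEV; generate `n_repeats` temporally shuffled surrogates and do the
#' same (refitting per surrogate by default, or backfitting the real model
#' when `refit = FALSE`). Both groups are screened with
#' [mad_outlier_filter()], each is tested for normality (one-sample
#' Kolmogorov-Smirnov on standardized values) and the groups are compared
#' with a two-sample Kolmogorov-Smirnov test. If microstate structure is
#' real, totGEV should drop substantially after shuffling.
#'
#' @param recordings list of [recording()]s (>= 2).
#' @param k number of microstate classes.
#' @param n_repeats surrogates per recording (default 10).
#' @param seed master seed.
#' @param refit refit a model per surrogate (default) or backfit the real
#'   model.
#' @param percent report GEVs in percent instead of fractions.
#' @return An object of class `gev_contrast`: `real_gevs`,
#'   `surrogate_gevs`, outlier masks, group means/SDs, and `tests` (KS
#'   normality per group + two-sample KS).
#' @export
gev_contrast <- function(recordings, k, n_repeats = 10L, seed = 1L,
                         refit = TRUE, percent = FALSE) {
  if (length(recordings) < 2L) stop_invalid("need at least 2 recordings")
  if (nrow(recordings[[1L]]$data) < 2L)
    stop_invalid("contrast needs multichannel recordings")
  real <- numeric(length(recordings))
  surr <- numeric(0)
  for (i in seq_along(recordings)) {
    rec <- average_reference(recordings[[i]])
    fit <- fit_microstates(rec, k_min = k, k_max = k)
    model <- fit$models[[as.character(k)]]
    real[i] <- compute_gev(rec, model)$tot_gev
    surrogates <- shuffle_recording(rec, n_repeats,
                                    seed = child_seed(seed, 11L, i))
    surr <- c(surr, vapply(surrogates, function(s)
      .rec_totgev(s, k, model = if (refit) NULL else model), 0))
  }
  if (percent) { real <- 100 * real; surr <- 100 * surr }
  fr <- mad_outlier_filter(real)
  fs_ <- mad_outlier_filter(surr)
  if (!length(fr$values) || !length(fs_$values))
    stop(structure(class = c("ratstates_invalid_state", "error", "condition"),
                   list(message = "a group was emptied by outlier filtering",
                        call = sys.call(-1))))
  norm_test <- function(x) {
    if (length(x) <= 3L)
      return(structure(class = "ratstates_too_few_samples",
                       list(message = "too few samples for a normality test",
                            n = length(x))))
    suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm"))
  }
  two <- suppressWarnings(ks.test(fr$values, fs_$values))
  structure(list(real_gevs = real, surrogate_gevs = surr,
                 real_mask = fr$mask, surrogate_mask = fs_$mask,
                 real_mean = mean(fr$values), real_sd = sd(fr$values),
                 surrogate_mean = mean(fs_$values),
                 surrogate_sd = sd(fs_$values),
                 tests = list(normality_real = norm_test(fr$values),
                              normality_surrogate = norm_test(fs_$values),
                              two_sample = two),
                 k = k, percent = percent),
            class = "gev_contrast")
}

#' @export
print.gev_contrast <- function(x, ...) {
  u <- if (x$percent) "%" else ""
  cat("<gev_contrast> K = ", x$k, "\n",
      "  real:      ", round(x$real_mean, 4), u, " +/- ",
      round(x$real_sd, 4), " (n = ", sum(x$real_mask), ")\n",
      "  surrogate: ", round(x$surrogate_mean, 4), u, " +/- ",
      round(x$surrogate_sd, 4), " (n = ", sum(x$surrogate_mask), ")\n",
      "  two-sample KS: D = ", round(x$tests$two_sample$statistic, 4),
      ", p = ", format(x$tests$two_sample$p.value, digits = 3), "\n",
      sep = "")
  invisible(x)
}
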