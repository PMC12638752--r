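#' Backfit microstate templates to a recording
#'
#' Every sample is assigned to the template map with the highest absolute
#' spatial correlation (polarity ignored). Ties break to the lowest class
#' index; samples with zero GFP carry no topography and are left
#' unassigned (`NA`).
#'
#' @param rec an [recording()].
#' @param model a `microstate_model` (channel count must match).
#' @return An object of class `label_sequence`: list with `labels`
#'   (integer per sample, `NA` where GFP = 0), `correlations` (per-sample
#'   `|r|` to the winning map), `k`, and `fs`.
#' @export
backfit <- function(rec, model) {
  maps <- model$maps
  if (ncol(maps) != nrow(rec$data))
    stop_invalid("model channel count does not match recording")
  X <- rec$data
  X <- X - rep(colMeans(X), each = nrow(X))
  nrm <- sqrt(colSums(X^2))
  nz <- nrm > 0
  Xn <- X
  Xn[, nz] <- X[, nz, drop = FALSE] / rep(nrm[nz], each = nrow(X))
  # maps rows are zero-mean unit-norm, so |Pearson r| = |inner product|
  R <- abs(crossprod(Xn, t(maps)))        # T x K
  lab <- max.col(R, ties.method = "first")
  corr <- R[cbind(seq_len(nrow(R)), lab)]
  lab[!nz] <- NA_integer_
  corr[!nz] <- NA_real_
  structure(list(labels = lab, correlations = corr, k = model$k,
                 fs = rec$fs),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat("<label_sequence> ", length(x$labels), " samples, K = ", x$k,
      ", unassigned = ", sum(is.na(x$labels)), "\n", sep = "")
  invisible(x)
}

#' Global explained variance of a labelled recording
#'
#' For class k, `GEV_k = sum_i GFP_i^2 C_{ik}^2 [L_i = k] / sum_i GFP_i^2`,
#' where `C_{ik}` is the spatial correlation between the topography at
#' sample i and map k, and the sum runs over the evaluation samples — GFP
#' peaks by default (`on = "peaks"`), or every sample (`on = "all"`).
#' `totGEV = sum_k GEV_k`.
#'
#' @param rec an [recording()].
#' @param model a `microstate_model`.
#' @param labels a `label_sequence` from [backfit()] on the same recording
#'   (computed if missing).
#' @param on evaluate on `"peaks"` (default) or `"all"` samples.
#' @return List with `gev_k` (length K) and `tot_gev`.
#' @export
compute_gev <- function(rec, model, labels = NULL, on = c("peaks", "all")) {
  on <- match.arg(on)
  if (is.null(labels)) labels <- backfit(rec, model)
  if (length(labels$labels) != ncol(rec$data))
    stop_invalid("labels do not match the recording length")
  gfp <- compute_gfp(rec)
  idx <- if (on == "peaks") gfp$peak_indices else seq_along(gfp$values)
  if (!length(idx) || all(gfp$values[idx] == 0))
    stop(structure(class = c("ratstates_undefined_gev", "error", "condition"),
                   list(message = "GEV undefined: no nonzero-GFP samples",
                        call = sys.call(-1))))
  w <- gfp$values[idx]^2
  lab <- labels$labels[idx]
  corr2 <- labels$correlations[idx]^2
  keep <- !is.na(lab)
  gev_k <- vapply(seq_len(model$k), function(k) {
    s <- keep & lab == k
    sum(w[s] * corr2[s])
  }, 0) / sum(w)
  list(gev_k = gev_k, tot_gev = sum(gev_k))
}
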