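#' Atomize-and-agglomerate hierarchical clustering of GFP-peak maps
#'
#' AAHC starts from every peak topography as its own cluster and repeatedly
#' (i) identifies the cluster contributing least to the global explained
#' variance (GEV), (ii) dissolves it, and (iii) reassigns each orphaned map
#' to the surviving cluster whose template it correlates with most strongly
#' in absolute value. Cluster templates are the first principal spatial
#' component of the member maps (a polarity-invariant mean). One model is
#' retained for every K in `k_min:k_max`. The procedure is deterministic
#' given the input order.
#'
#' @param peak_maps P x C matrix of topographies at GFP peaks (rows = peaks).
#' @param gfp_at_peaks numeric vector of GFP values at those peaks.
#' @param k_min,k_max range of cluster counts to retain (defaults 2 and 10).
#' @return An object of class `aahc_fit`: a list with `models` (one
#'   `microstate_model` per K, named by K), `k_values`, and `n_peaks`.
#'   Each model carries `maps` (K x C, zero-mean unit-norm rows), `k`,
#'   `training_gev` (totGEV on the training peaks), `gev_k`, `assignments`
#'   (per-peak cluster index) and `provenance`.
#' @export
aahc_cluster <- function(peak_maps, gfp_at_peaks, k_min = 2L, k_max = 10L) {
  peak_maps <- as.matrix(peak_maps)
  P <- nrow(peak_maps); C <- ncol(peak_maps)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max < k_min)
    stop_invalid("need 1 <= k_min <= k_max")
  if (P <= k_max)
    stop_invalid("number of peaks (", P, ") must exceed k_max (", k_max, ")")
  if (length(gfp_at_peaks) != P)
    stop_invalid("gfp_at_peaks must have one value per peak")

  U <- normalize_maps(peak_maps)           # rows zero-mean, unit norm
  w <- as.numeric(gfp_at_peaks)^2          # GEV weights
  w_tot <- sum(w)

  # state: active clusters, per-peak assignment, templates, contributions
  assign_ <- seq_len(P)
  templates <- U                           # row i = template of cluster i
  contrib <- w  # singleton contribution is w_p: |corr(u_p, u_p)| = 1
  active <- rep(TRUE, P)
  n_active <- P
  members <- as.list(seq_len(P))

  recompute_cluster <- function(cl) {
    idx <- members[[cl]]
    tpl <- principal_map(U[idx, , drop = FALSE])
    templates[cl, ] <<- tpl
    contrib[cl] <<- sum(w[idx] * as.numeric(U[idx, , drop = FALSE] %*% tpl)^2)
  }

  models <- list()
  snapshot <- function() {
    ids <- which(active)
    remap <- integer(P); remap[ids] <- seq_along(ids)
    maps <- templates[ids, , drop = FALSE]
    a <- remap[assign_]
    corr2 <- rowSums(U * maps[a, , drop = FALSE])^2
    gev_k <- vapply(seq_along(ids), function(k)
      sum(w[a == k] * corr2[a == k]) / w_tot, 0)
    rownames(maps) <- paste0("MS", seq_along(ids))
    if (!is.null(colnames(peak_maps))) colnames(maps) <- colnames(peak_maps)
    structure(list(maps = maps, k = length(ids),
                   training_gev = sum(gev_k), gev_k = gev_k,
                   assignments = a,
                   provenance = list(algorithm = "AAHC", n_peaks = P)),
              class = "microstate_model")
  }

  while (TRUE) {
    if (n_active <= k_max)
      models[[as.character(n_active)]] <- snapshot()
    if (n_active == k_min) break
    ids <- which(active)
    worst <- ids[which.min(contrib[ids])]
    orphans <- members[[worst]]
    active[worst] <- FALSE
    n_active <- n_active - 1L
    members[[worst]] <- integer(0)
    ids <- which(active)
    sim <- abs(U[orphans, , drop = FALSE] %*% t(templates[ids, , drop = FALSE]))
    dest <- ids[max.col(sim, ties.method = "first")]
    assign_[orphans] <- dest
    for (cl in unique(dest)) {
      members[[cl]] <- c(members[[cl]], orphans[dest == cl])
      recompute_cluster(cl)
    }
  }
  structure(list(models = rev(models),
                 k_values = sort(as.integer(names(models))),
                 n_peaks = P),
            class = "aahc_fit")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("<microstate_model> K = ", x$k, ", training totGEV = ",
      round(x$training_gev, 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.aahc_fit <- function(x, ...) {
  cat("<aahc_fit> K in {", paste(x$k_values, collapse = ", "),
      "} over ", x$n_peaks, " GFP-peak maps\n", sep = "")
  invisible(x)
}

#' Fit microstate models to a recording
#'
#' Convenience wrapper: GFP, peak extraction, and [aahc_cluster()] on the
#' peak topographies.
#'
#' @param rec an [recording()] (average-referenced).
#' @param k_min,k_max cluster-count range.
#' @return An `aahc_fit` with the `gfp_series` attached as attribute "gfp".
#' @export
fit_microstates <- function(rec, k_min = 2L, k_max = 10L) {
  rec <- average_reference(rec)
  gfp <- compute_gfp(rec)
  pk <- gfp$peak_indices
  if (length(pk) <= k_max)
    stop_invalid("too few GFP peaks (", length(pk), ") for k_max = ", k_max)
  fit <- aahc_cluster(t(rec$data[, pk, drop = FALSE]), gfp$values[pk],
                      k_min, k_max)
  attr(fit, "gfp") <- gfp
  fit
}
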