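# Polarity-invariant distance between unit-norm zero-mean topographies:
# d(u, v) = 1 - |r(u, v)|, with r the Pearson correlation across channels.
# All criteria below use it so that a map and its negation coincide.
.pdist <- function(U) {
  R <- abs(tcrossprod(U))
  d <- 1 - pmin(R, 1)
  diag(d) <- 0
  d
}

#' Within-cluster dispersion W(K)
#'
#' Sum over clusters of the mean pairwise squared polarity-invariant
#' distance between member maps, scaled by cluster size. Singleton clusters
#' contribute zero; with every point its own cluster W = 0. On nested AAHC
#' solutions W is non-increasing in K.
#'
#' @param peak_maps P x C matrix of peak topographies.
#' @param assignments integer vector of cluster indices per peak.
#' @return The scalar dispersion W.
#' @export
cluster_dispersion <- function(peak_maps, assignments) {
  U <- normalize_maps(as.matrix(peak_maps))
  if (length(assignments) != nrow(U))
    stop_invalid("one assignment per peak required")
  ks <- sort(unique(assignments))
  tot <- 0
  for (k in ks) {
    idx <- which(assignments == k)
    if (!length(idx))
      stop(structure(class = c("ratstates_invalid_state", "error",
                               "condition"),
                     list(message = "empty cluster", call = sys.call(-1))))
    n <- length(idx)
    if (n < 2L) next
    d <- .pdist(U[idx, , drop = FALSE])
    tot <- tot + n * mean(d[upper.tri(d)]^2)
  }
  tot
}

#' Krzanowski-Lai criterion
#'
#' `DIFF(K) = (K-1)^(2/m) W(K-1) - K^(2/m) W(K)` with m the channel count
#' (maps live in channel space), and `KL(K) = |DIFF(K)| / |DIFF(K+1)|`.
#' The optimum is the interior K maximising KL; endpoints of the K range
#' are excluded by construction.
#'
#' @param W numeric vector of dispersions aligned with `k_values`.
#' @param k_values contiguous increasing candidate K values.
#' @param m feature dimension (number of channels).
#' @return List with `scores` (named by K, `NA` at the endpoints) and
#'   `chosen_k`.
#' @export
kl_criterion <- function(W, k_values, m) {
  k_values <- as.integer(k_values)
  if (length(W) != length(k_values))
    stop_invalid("W and k_values lengths differ")
  if (length(k_values) < 3L || any(diff(k_values) != 1L))
    stop_invalid("need a contiguous K range of length >= 3")
  p <- 2 / m
  n <- length(k_values)
  DIFF <- rep(NA_real_, n)
  for (i in 2:n)
    DIFF[i] <- (k_values[i] - 1)^p * W[i - 1L] - k_values[i]^p * W[i]
  scores <- rep(NA_real_, n)
  for (i in 2:(n - 1L))
    scores[i] <- abs(DIFF[i]) / abs(DIFF[i + 1L])
  names(scores) <- k_values
  interior <- which(!is.na(scores))
  chosen <- k_values[interior[which.max(scores[interior])]]
  list(scores = scores, diff = DIFF, chosen_k = chosen)
}

#' Cross-validation criterion
#'
#' Predictive residual variance penalised by the channel count:
#' `CV(K) = sigma2_K * ((C-1)/(C-1-K))^2`, where `sigma2_K` is the mean
#' unexplained variance of the peak topographies given their assigned
#' templates, `sigma2_K = sum_i (x_i'x_i - (t_{L_i}'x_i)^2) / (N (C-1))`.
#' Smaller is better.
#'
#' @param peak_maps P x C matrix of raw (average-referenced) peak maps.
#' @param fit an `aahc_fit` over the same peaks.
#' @return List with `scores` (named by K) and `chosen_k` (argmin).
#' @export
cv_criterion <- function(peak_maps, fit) {
  X <- as.matrix(peak_maps)
  X <- X - rowMeans(X)
  C <- ncol(X)
  ks <- fit$k_values
  if (any(ks >= C - 1L))
    stop_invalid("CV undefined for K >= C-1 (C = ", C, ")")
  scores <- vapply(ks, function(K) {
    mod <- fit$models[[as.character(K)]]
    a <- mod$assignments
    proj <- rowSums(X * mod$maps[a, , drop = FALSE])
    sigma2 <- sum(rowSums(X^2) - proj^2) / (nrow(X) * (C - 1))
    sigma2 * ((C - 1) / (C - 1 - K))^2
  }, 0)
  names(scores) <- ks
  list(scores = scores, chosen_k = ks[which.min(scores)])
}

#' Davies-Bouldin, Dunn and Frey-Van Groenewoud criteria
#'
#' Standard cluster-validity indices computed on the polarity-invariant
#' distance `d(u, v) = 1 - |r(u, v)|`:
#' * Davies-Bouldin (minimise): mean over clusters of the worst
#'   `(S_i + S_j) / d(t_i, t_j)`, with `S_i` the mean member-to-template
#'   distance;
#' * Dunn (maximise): smallest between-cluster point distance over the
#'   largest cluster diameter;
#' * Frey-Van Groenewoud (best where closest to 1): ratio of successive
#'   differences in mean between-template and mean within-cluster distance
#'   between levels K and K+1.
#'
#' @param peak_maps P x C matrix of peak topographies.
#' @param fit an `aahc_fit`.
#' @return List of per-criterion score vectors (named by K) and the
#'   per-criterion `chosen_k`.
#' @export
auxiliary_criteria <- function(peak_maps, fit) {
  U <- normalize_maps(as.matrix(peak_maps))
  ks <- fit$k_values
  level <- function(K) {
    mod <- fit$models[[as.character(K)]]
    a <- mod$assignments
    Tm <- mod$maps
    dt <- 1 - pmin(abs(tcrossprod(U, Tm)), 1)      # point-to-template
    S <- vapply(seq_len(K), function(k) {
      idx <- a == k
      if (!any(idx)) 0 else mean(dt[idx, k])
    }, 0)
    M <- .pdist(Tm)
    # Davies-Bouldin
    db <- if (K < 2L) NA_real_ else mean(vapply(seq_len(K), function(i) {
      max(vapply(setdiff(seq_len(K), i), function(j)
        (S[i] + S[j]) / max(M[i, j], .Machine$double.eps), 0))
    }, 0))
    # Dunn
    dunn <- NA_real_
    if (K >= 2L) {
      D <- .pdist(U)
      diam <- max(vapply(seq_len(K), function(k) {
        idx <- which(a == k)
        if (length(idx) < 2L) 0
        else max(D[idx, idx])
      }, 0))
      sep <- min(vapply(seq_len(K - 1L), function(i) {
        min(vapply((i + 1L):K, function(j)
          min(D[a == i, a == j]), 0))
      }, 0))
      dunn <- if (diam == 0) {
        warning("Dunn undefined: all clusters are singletons or identical")
        NA_real_
      } else sep / diam
    }
    within <- mean(dt[cbind(seq_len(nrow(U)), a)])
    between <- if (K < 2L) NA_real_ else mean(M[upper.tri(M)])
    c(db = db, dunn = dunn, within = within, between = between)
  }
  tab <- vapply(ks, level, c(db = 0, dunn = 0, within = 0, between = 0))
  db <- tab["db", ]; dunn <- tab["dunn", ]
  fvg <- rep(NA_real_, length(ks))
  for (i in seq_len(length(ks) - 1L)) {
    dw <- tab["within", i + 1L] - tab["within", i]
    dbw <- tab["between", i + 1L] - tab["between", i]
    fvg[i] <- if (dw == 0) NA_real_ else dbw / dw
  }
  names(db) <- names(dunn) <- names(fvg) <- ks
  list(db = db, dunn = dunn, fvg = fvg,
       chosen_k = c(db = ks[which.min(db)],
                    dunn = ks[which.max(dunn)],
                    fvg = ks[which.min(abs(fvg - 1))]))
}

#' Criterion table over candidate K
#'
#' Runs every implemented selection criterion on an `aahc_fit` and returns
#' the per-K scores together with each criterion's preferred K. The
#' "dispersion" column is W(K) itself, reported directly.
#'
#' @param peak_maps P x C matrix of raw peak topographies.
#' @param fit an `aahc_fit` over those peaks.
#' @return A `criterion_table` data.frame (one row per K, one column per
#'   criterion) with attribute `chosen_k`, a named integer vector.
#' @export
criterion_table <- function(peak_maps, fit) {
  ks <- fit$k_values
  W <- vapply(ks, function(K)
    cluster_dispersion(peak_maps, fit$models[[as.character(K)]]$assignments),
    0)
  m <- ncol(fit$models[[1L]]$maps)
  kl <- kl_criterion(W, ks, m)
  cv <- cv_criterion(peak_maps, fit)
  aux <- auxiliary_criteria(peak_maps, fit)
  out <- data.frame(k = ks, dispersion = W, kl = unname(kl$scores),
                    cv = unname(cv$scores), db = unname(aux$db),
                    dunn = unname(aux$dunn), fvg = unname(aux$fvg))
  chosen <- c(kl = kl$chosen_k, cv = cv$chosen_k, aux$chosen_k)
  attr(out, "chosen_k") <- chosen
  class(out) <- c("criterion_table", "data.frame")
  out
}

#' Metacriterion: median vote over criteria
#'
#' Takes the per-criterion optimal K values and returns their median; with
#' an even number of votes the lower middle value is used (ties break to
#' the smaller K).
#'
#' @param table a `criterion_table`, or a named vector of per-criterion
#'   chosen K values.
#' @param criteria which criteria vote (default: all present).
#' @return The chosen K (integer).
#' @export
metacriterion_select <- function(table, criteria = NULL) {
  votes <- if (inherits(table, "criterion_table")) attr(table, "chosen_k")
           else table
  if (!is.null(criteria)) votes <- votes[criteria]
  votes <- votes[!is.na(votes)]
  if (length(votes) < 1L) stop_invalid("no criteria to vote")
  v <- sort(as.integer(votes))
  v[ceiling(length(v) / 2)]   # lower median: ties go to the smaller K
}
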