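#' Frequency band definitions
#'
#' The band set used when associating microstate time courses with
#' source-space power: delta 2-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta
#' (low/mid) 12-20 Hz, plus unfiltered broadband.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz; `NA` for
#'   broadband).
#' @export
eeg_bands <- function() .band_table()

# Analytic signal via FFT: x + i * H(x). Standard construction (double the
# positive frequencies, zero the negative ones).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-limited power envelope
#'
#' Band-pass the series with a two-pass (zero-phase) Butterworth filter of
#' order 3 and take the magnitude of the analytic signal (Hilbert
#' envelope). `"broadband"` skips the filtering.
#'
#' @param series numeric vector, or S x T matrix (one series per row).
#' @param band a band name from [eeg_bands()], or a list/row with `lo`,
#'   `hi` in Hz.
#' @param fs sampling rate in Hz.
#' @return Envelope with the same shape as `series`.
#' @export
band_envelope <- function(series, band, fs) {
  if (is.character(band)) {
    tab <- .band_table()
    if (!band %in% tab$name)
      stop_invalid("unknown band '", band, "'")
    band <- tab[tab$name == band, ]
  }
  one <- function(x) {
    if (!is.na(band$lo)) {
      if (!(band$lo > 0 && band$hi > band$lo && band$hi < fs / 2))
        stop_invalid("band outside (0, Nyquist)")
      bf <- signal::butter(3, c(band$lo, band$hi) / (fs / 2), type = "pass")
      x <- signal::filtfilt(bf, x)
    }
    Mod(analytic_signal(x))
  }
  if (is.matrix(series)) t(apply(series, 1L, one)) else one(series)
}

#' Global map dissimilarity
#'
#' GMD between consecutive samples: the root-mean-square channel difference
#' of the GFP-normalized topographies, in `[0, 2]` (0 = same shape,
#' sqrt(2) = orthogonal, 2 = opposite polarity). The first sample and any
#' pair involving a zero-GFP sample are `NA`.
#'
#' @param rec an [recording()] (average-referenced defensively).
#' @return Numeric vector of per-sample GMD values (`NA` at sample 1).
#' @export
compute_gmd <- function(rec) {
  X <- rec$data
  X <- X - rep(colMeans(X), each = nrow(X))
  gfp <- sqrt(colMeans(X^2))
  U <- X
  nz <- gfp > 0
  U[, nz] <- X[, nz, drop = FALSE] / rep(gfp[nz], each = nrow(X))
  U[, !nz] <- NA_real_
  d <- sqrt(colMeans((U[, -1L, drop = FALSE] -
                        U[, -ncol(U), drop = FALSE])^2))
  unname(c(NA_real_, d))
}

#' Build microstate regressors for source association
#'
#' For each class k the regressor is `b_k(t) = |x_t . map_k|`, the absolute
#' inner product of the (average-referenced) sample with the unit-norm
#' template — a continuous measure of how strongly the map is expressed,
#' invariant to recording polarity. GFP and GMD nuisance series are
#' included; undefined GMD entries are set to 0 so designs stay complete.
#'
#' @param rec an [recording()].
#' @param model a `microstate_model` with matching channels.
#' @param standardize z-score each regressor? (default FALSE; emitted raw)
#' @return An object of class `regressor_set`: list with `b` (T x K
#'   matrix), `gfp`, `gmd`, `fs`, `standardized`.
#' @export
build_regressors <- function(rec, model, standardize = FALSE) {
  if (ncol(model$maps) != nrow(rec$data))
    stop_invalid("model channel count does not match recording")
  X <- rec$data
  X <- X - rep(colMeans(X), each = nrow(X))
  B <- abs(crossprod(X, t(model$maps)))   # T x K
  colnames(B) <- rownames(model$maps)
  gfp <- sqrt(colMeans(X^2))
  gmd <- compute_gmd(rec)
  gmd[!is.finite(gmd)] <- 0
  if (standardize) {
    z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
    B <- apply(B, 2L, z); gfp <- z(gfp); gmd <- z(gmd)
  }
  structure(list(b = B, gfp = gfp, gmd = gmd, fs = rec$fs,
                 standardized = standardize),
            class = "regressor_set")
}

#' Per-source linear model of band-limited power
#'
#' Ordinary least squares of each source's BLP envelope on the microstate
#' regressor plus nuisance terms:
#' `BLP = b0 + b1 * B_k + b2 * GFP + b3 * GMD + e`. The coefficient of
#' interest is `b1`, returned per source.
#'
#' @param blp S x T matrix (or vector) of band-limited power envelopes.
#' @param regs a `regressor_set`.
#' @param k microstate class index selecting the column of `regs$b`.
#' @param trim_s seconds to drop from each end of the series before
#'   fitting (default 0). Band-pass filtering and the Hilbert transform
#'   deform envelopes near the recording edges — systematically so across
#'   subjects sharing one regressor set — and trimming the transient
#'   removes that bias from the group test.
#' @return List with `beta1` (length S), `coefficients` (4 x S), and
#'   `rank_deficient` (logical; coefficients are `NA` when the design is
#'   rank deficient).
#' @export
fit_source_glm <- function(blp, regs, k, trim_s = 0) {
  if (is.vector(blp)) blp <- matrix(blp, nrow = 1L)
  n <- ncol(blp)
  if (length(regs$gfp) != n)
    stop_invalid("envelope and regressors are not aligned")
  keep <- seq_len(n)
  if (trim_s > 0) {
    drop_n <- floor(trim_s * regs$fs)
    if (2L * drop_n >= n - 10L)
      stop_invalid("trim_s leaves too few samples")
    keep <- (drop_n + 1L):(n - drop_n)
    blp <- blp[, keep, drop = FALSE]
    n <- length(keep)
  }
  D <- cbind(intercept = 1, b_k = regs$b[keep, k], gfp = regs$gfp[keep],
             gmd = regs$gmd[keep])
  if (n - ncol(D) < 5L)
    stop_invalid("need at least 5 more samples than parameters")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("rank-deficient design; coefficients undefined")
    return(list(beta1 = rep(NA_real_, nrow(blp)),
                coefficients = matrix(NA_real_, 4L, nrow(blp)),
                rank_deficient = TRUE))
  }
  coefs <- qr.coef(qrD, t(blp))           # 4 x S
  list(beta1 = unname(coefs["b_k", ]), coefficients = coefs,
       rank_deficient = FALSE)
}

# Normalise a graph argument to an igraph object.
.as_graph <- function(graph, n) {
  if (igraph::is_igraph(graph)) g <- graph
  else g <- igraph::graph_from_adjacency_matrix(as.matrix(graph) != 0,
                                                mode = "undirected",
                                                diag = FALSE)
  if (igraph::vcount(g) != n)
    stop_invalid("graph has ", igraph::vcount(g), " nodes, expected ", n)
  g
}

#' Threshold-free cluster enhancement
#'
#' For each node, integrates `extent^E * h^H dh` over thresholds h from 0
#' up to the node's statistic value, where `extent` is the size of the
#' supra-threshold connected component the node belongs to at threshold h.
#' Negative values are enhanced on the negated map and returned with a
#' negative sign (two-sided enhancement).
#'
#' @param stat numeric per-node statistic.
#' @param graph an `igraph` graph or adjacency matrix over the nodes.
#' @param e_exp extent exponent E (default 0.5).
#' @param h_exp height exponent H (default 2).
#' @param n_steps number of integration steps over `(0, max|stat|]`
#'   (default 100); midpoint rule.
#' @param dh explicit step size, overriding `n_steps`.
#' @return Numeric vector of signed enhanced values.
#' @export
tfce_enhance <- function(stat, graph, e_exp = 0.5, h_exp = 2,
                         n_steps = 100L, dh = NULL) {
  if (!all(is.finite(stat))) stop_invalid("statistics must be finite")
  g <- .as_graph(graph, length(stat))
  one_side <- function(v) {
    hmax <- max(v)
    if (hmax <= 0) return(numeric(length(v)))
    step <- if (!is.null(dh)) dh else hmax / n_steps
    hs <- seq(step / 2, hmax, by = step)
    enh <- numeric(length(v))
    for (h in hs) {
      sup <- which(v >= h)
      if (!length(sup)) break
      comp <- igraph::components(igraph::induced_subgraph(g, sup))
      ext <- comp$csize[comp$membership]
      enh[sup] <- enh[sup] + ext^e_exp * h^h_exp * step
    }
    enh
  }
  one_side(pmax(stat, 0)) - one_side(pmax(-stat, 0))
}

#' Group-level sign-flip permutation test with TFCE correction
#'
#' Tests where the per-source group effect (e.g. the `beta1` coefficients
#' of [fit_source_glm()] across subjects) differs from zero. The observed
#' one-sample t map is TFCE-enhanced; the null distribution of the maximum
#' absolute enhanced value is built by randomly sign-flipping whole subject
#' maps, giving family-wise-corrected two-sided p-values.
#'
#' @param beta1 subjects x sources matrix of per-subject effects.
#' @param graph source neighbourhood graph (igraph or adjacency matrix).
#' @param alpha two-sided family-wise significance level (default 0.001).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param seed integer seed.
#' @param e_exp,h_exp,n_steps TFCE parameters (see [tfce_enhance()]).
#' @return An object of class `stat_map`: `beta1` (group mean), `tstat`,
#'   `enhanced`, `p` (corrected), `signif_mask`, `alpha`, `n_perm`.
#' @export
group_permutation_test <- function(beta1, graph, alpha = 0.001,
                                   n_perm = 1000L, seed = 1L,
                                   e_exp = 0.5, h_exp = 2, n_steps = 50L) {
  beta1 <- as.matrix(beta1)
  n_sub <- nrow(beta1); n_src <- ncol(beta1)
  if (n_sub < 6L)
    stop(structure(class = c("ratstates_too_few_subjects", "error",
                             "condition"),
                   list(message = paste0("sign-flip test needs >= 6 subjects, got ",
                                         n_sub),
                        call = sys.call(-1))))
  g <- .as_graph(graph, n_src)
  tmap <- function(B) {
    mu <- colMeans(B)
    se <- apply(B, 2L, sd) / sqrt(nrow(B))
    t_ <- mu / se
    t_[!is.finite(t_)] <- 0
    t_
  }
  obs_t <- tmap(beta1)
  obs_enh <- tfce_enhance(obs_t, g, e_exp, h_exp, n_steps)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    enh <- tfce_enhance(tmap(beta1 * flips), g, e_exp, h_exp, n_steps)
    max(abs(enh))
  }, 0))
  p <- vapply(abs(obs_enh), function(e)
    (1 + sum(null_max >= e)) / (n_perm + 1), 0)
  structure(list(beta1 = colMeans(beta1), tstat = obs_t,
                 enhanced = obs_enh, p = p, signif_mask = p <= alpha,
                 alpha = alpha, n_perm = n_perm, null_max = null_max),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$p), " sources, ", sum(x$signif_mask),
      " significant at alpha = ", x$alpha, " (", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Summaries over a set of statistical maps
#'
#' For each (microstate, band) statistical map: the cluster-size fraction
#' (significant sources / total sources) and the pairwise Pearson
#' correlation matrix of the TFCE-masked enhanced maps. Maps without any
#' significant source get fraction 0 and are omitted from the correlation
#' matrix. Each pairwise correlation is computed on the union of the two
#' maps' masked supports (enhanced values outside a map's own mask count
#' as 0).
#'
#' @param maps named list of `stat_map`s sharing a source space.
#' @return List with `fractions` (named numeric) and `correlations`
#'   (matrix over the significant maps, possibly 0 x 0).
#' @export
summarize_statmaps <- function(maps) {
  if (!length(maps)) stop_invalid("empty map set")
  n_src <- length(maps[[1L]]$p)
  for (m in maps) if (length(m$p) != n_src)
    stop_invalid("maps do not share a source space")
  if (is.null(names(maps)))
    names(maps) <- paste0("map", seq_along(maps))
  fractions <- vapply(maps, function(m) mean(m$signif_mask), 0)
  sig <- names(maps)[fractions > 0]
  cormat <- matrix(numeric(0), 0L, 0L)
  if (length(sig)) {
    masked <- lapply(maps[sig], function(m) {
      v <- m$enhanced
      v[!m$signif_mask] <- 0
      v
    })
    cormat <- matrix(NA_real_, length(sig), length(sig),
                     dimnames = list(sig, sig))
    for (i in seq_along(sig)) for (j in seq_along(sig)) {
      supp <- maps[[sig[i]]]$signif_mask | maps[[sig[j]]]$signif_mask
      cormat[i, j] <- if (sum(supp) >= 3L)
        cor(masked[[i]][supp], masked[[j]][supp]) else NA_real_
    }
  }
  list(fractions = fractions, correlations = cormat)
}

#' Reduce three-orientation source series to one
#'
#' Utility for users bringing their own inverse solutions: projects the
#' three dipole-orientation time series of a source onto their first
#' principal component.
#'
#' @param xyz 3 x T matrix of orientation time series.
#' @return Numeric vector of length T.
#' @export
pc_reduce <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != 3L) stop_invalid("expected a 3 x T matrix")
  xc <- xyz - rowMeans(xyz)
  v <- eigen(tcrossprod(xc), symmetric = TRUE)$vectors[, 1L]
  as.numeric(crossprod(xc, v))
}
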