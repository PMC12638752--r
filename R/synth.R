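#' Ground truth for synthetic microstate recordings
#'
#' Bundles everything needed to simulate a recording with known microstate
#' structure: K template topographies, the dwell-time distribution, the
#' between-state transition matrix, the GFP-modulating amplitude process and
#' the sensor-noise scale. Template maps are average-reference compatible
#' (zero channel mean) and unit norm; by default they are mutually
#' orthogonalized, with `map_correlation` allowing controlled overlap since
#' empirical microstate maps are inter-correlated.
#'
#' @param n_states number of microstate classes K.
#' @param montage a [montage]; maps live in its channel space.
#' @param mean_dwell_s mean state dwell time in seconds (default 0.1 s,
#'   i.e. dwellings of tens to hundreds of ms).
#' @param dwell_shape gamma shape of the dwell distribution (default 2:
#'   strictly positive, unimodal).
#' @param transition_matrix optional K x K row-stochastic matrix with zero
#'   diagonal; default is uniform over the other states.
#' @param map_correlation target pairwise correlation between template maps
#'   in `[0, 1)`; 0 gives orthogonal maps.
#' @param amp_freq_hz frequency of the rectified oscillatory GFP envelope
#'   (default 10 Hz, guaranteeing dense GFP peaks).
#' @param noise_sd sensor-noise standard deviation (µV); see also the `snr`
#'   argument of [simulate_recording()].
#' @param seed integer seed; map generation is reproducible from it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_states, montage, mean_dwell_s = 0.1,
                         dwell_shape = 2, transition_matrix = NULL,
                         map_correlation = 0, amp_freq_hz = 10,
                         noise_sd = 1, seed = 1L) {
  n_states <- as.integer(n_states)
  if (n_states < 1L) stop_invalid("n_states must be >= 1")
  if (mean_dwell_s <= 0 || dwell_shape <= 0)
    stop_invalid("dwell parameters must be positive")
  if (map_correlation < 0 || map_correlation >= 1)
    stop_invalid("map_correlation must be in [0, 1)")
  C <- length(montage$channel_names)
  if (n_states > C - 1L)
    stop_invalid("cannot place ", n_states,
                 " orthogonal zero-mean maps in ", C, " channels")
  maps <- with_seed(seed, {
    raw <- matrix(rnorm(n_states * C), n_states, C)
    raw <- raw - rowMeans(raw)
    # Orthonormal basis of the zero-mean subspace spanned by the rows.
    q <- qr.Q(qr(t(raw)))[, seq_len(n_states), drop = FALSE]
    ortho <- t(q)
    ortho <- ortho - rowMeans(ortho)  # numerically re-center
    ortho <- normalize_maps(ortho)
    if (map_correlation > 0 && n_states > 1L) {
      common <- principal_map(ortho + matrix(rnorm(n_states * C, sd = 1e-6),
                                             n_states, C))
      lam <- sqrt(map_correlation)
      mixed <- (1 - lam) * ortho + lam * matrix(common, n_states, C,
                                                byrow = TRUE)
      ortho <- normalize_maps(mixed)
    }
    ortho
  })
  rownames(maps) <- paste0("MS", seq_len(n_states))
  colnames(maps) <- montage$channel_names
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(1L, n_states - 1L), n_states, n_states)
    diag(transition_matrix) <- 0
    if (n_states == 1L) transition_matrix <- matrix(0, 1L, 1L)
  } else {
    transition_matrix <- as.matrix(transition_matrix)
    if (!all(dim(transition_matrix) == n_states))
      stop_invalid("transition_matrix must be K x K")
    if (any(diag(transition_matrix) != 0))
      stop_invalid("transition_matrix must have zero diagonal")
    if (n_states > 1L &&
        any(abs(rowSums(transition_matrix) - 1) > 1e-8))
      stop_invalid("transition_matrix rows must sum to 1")
  }
  structure(list(maps = maps, n_states = n_states, montage = montage,
                 mean_dwell_s = mean_dwell_s, dwell_shape = dwell_shape,
                 transition_matrix = transition_matrix,
                 map_correlation = map_correlation,
                 amp_freq_hz = amp_freq_hz, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate a semi-Markov microstate label sequence
#'
#' States follow the embedded Markov chain of `truth$transition_matrix`;
#' each visit dwells for a gamma-distributed duration (shape
#' `truth$dwell_shape`, mean `truth$mean_dwell_s`), discretized at `fs`.
#' Every dwell occupies at least one sample.
#'
#' @param truth a [ground_truth].
#' @param duration_s total simulated duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed (defaults to `truth$seed`).
#' @return Integer vector of per-sample class labels in `1..K`.
#' @export
simulate_state_sequence <- function(truth, duration_s, fs, seed = NULL) {
  if (duration_s <= 0 || fs <= 0)
    stop_invalid("duration_s and fs must be positive")
  K <- truth$n_states
  P <- truth$transition_matrix
  if (K > 1L && any(rowSums(P) == 0))
    stop_invalid("transition matrix has an all-zero row: no exit state")
  n <- floor(duration_s * fs)
  if (is.null(seed)) seed <- child_seed(truth$seed, 101L)
  with_seed(seed, {
    labels <- integer(n)
    pos <- 1L
    state <- sample.int(K, 1L)
    scale <- truth$mean_dwell_s / truth$dwell_shape
    while (pos <= n) {
      dwell <- rgamma(1L, shape = truth$dwell_shape, scale = scale)
      len <- max(1L, round(dwell * fs))
      end <- min(n, pos + len - 1L)
      labels[pos:end] <- state
      pos <- end + 1L
      if (K > 1L)
        state <- sample.int(K, 1L, prob = P[state, ])
    }
    labels
  })
}

#' Simulate a multichannel recording from a planted label sequence
#'
#' Each sample is `amplitude(t) * map[label(t), ] + noise`, where the
#' amplitude is a rectified oscillation `|sin(2 pi f t)|` with a slow
#' multiplicative modulation, so GFP peaks occur densely within every dwell.
#' Sensor noise is drawn i.i.d. per channel and then re-centred per sample,
#' keeping the recording average-reference compatible by construction.
#'
#' @param truth a [ground_truth].
#' @param labels integer per-sample labels, e.g. from
#'   [simulate_state_sequence()].
#' @param fs sampling rate in Hz.
#' @param montage a [montage]; defaults to the one inside `truth`.
#' @param snr optional signal-to-noise ratio (RMS of noiseless signal over
#'   noise RMS); overrides `truth$noise_sd` when given.
#' @param seed integer seed (defaults to a child of `truth$seed`).
#' @return An [recording()] with the planted labels attached as attribute
#'   `"planted_labels"` and the amplitude series as `"amplitude"`.
#' @export
simulate_recording <- function(truth, labels, fs, montage = truth$montage,
                               snr = NULL, seed = NULL) {
  if (length(montage$channel_names) != ncol(truth$maps))
    stop_invalid("montage channel count does not match truth maps")
  if (any(labels < 1L | labels > truth$n_states))
    stop_invalid("labels outside 1..K")
  n <- length(labels)
  t_s <- (seq_len(n) - 1) / fs
  amp <- abs(sin(2 * pi * truth$amp_freq_hz * t_s)) *
    (1 + 0.3 * sin(2 * pi * 0.2 * t_s))
  signal <- t(truth$maps[labels, , drop = FALSE]) * rep(amp, each = ncol(truth$maps))
  dimnames(signal) <- NULL
  noise_sd <- truth$noise_sd
  if (!is.null(snr)) {
    if (snr <= 0) stop_invalid("snr must be positive")
    noise_sd <- sqrt(mean(signal^2)) / snr
  }
  if (is.null(seed)) seed <- child_seed(truth$seed, 202L)
  data <- with_seed(seed, {
    if (noise_sd > 0) {
      noise <- matrix(rnorm(length(signal), sd = noise_sd), nrow(signal))
      noise <- noise - rep(colMeans(noise), each = nrow(noise))
      signal + noise
    } else signal
  })
  rec <- recording(data, fs, montage)
  attr(rec, "planted_labels") <- labels
  attr(rec, "amplitude") <- amp
  rec
}

#' One-call synthetic recording
#'
#' Convenience wrapper reproducing the study conditions in one call:
#' montage, ground truth, label sequence and recording, all derived from a
#' single seed.
#'
#' @param n_channels montage size (default 19).
#' @param n_states number of classes (default 5).
#' @param duration_s duration in seconds.
#' @param fs sampling rate (default 250 Hz).
#' @param snr signal-to-noise ratio (default 5).
#' @param seed master seed.
#' @param ... further arguments passed to [ground_truth()].
#' @return The [recording()], with the `ground_truth` attached as attribute
#'   `"truth"`.
#' @export
simulate_dataset <- function(n_channels = 19L, n_states = 5L,
                             duration_s = 120, fs = 250, snr = 5,
                             seed = 1L, ...) {
  mont <- generate_montage(n_channels)
  truth <- ground_truth(n_states, mont, seed = child_seed(seed, 1L), ...)
  labels <- simulate_state_sequence(truth, duration_s, fs,
                                    seed = child_seed(seed, 2L))
  rec <- simulate_recording(truth, labels, fs, snr = snr,
                            seed = child_seed(seed, 3L))
  attr(rec, "truth") <- truth
  rec
}

#' Stationary coverage of a ground truth's semi-Markov process
#'
#' Long-run fraction of time in each state: proportional to the stationary
#' distribution of the embedded chain times the mean dwell (equal dwell
#' means across states here, so it reduces to the embedded stationary
#' distribution).
#'
#' @param truth a [ground_truth].
#' @return Numeric vector of length K summing to 1.
#' @export
stationary_coverage <- function(truth) {
  K <- truth$n_states
  if (K == 1L) return(1)
  P <- truth$transition_matrix
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

.band_table <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "broadband"),
             lo = c(2, 4, 8, 12, NA), hi = c(4, 8, 12, 20, NA),
             stringsAsFactors = FALSE)
}

#' Simulate a toy source scene
#'
#' Sources are laid out on a rectangular grid (3-D positions with z = 0)
#' with 4-neighbour adjacency. Each source carries band-limited Gaussian
#' noise whose instantaneous amplitude is modulated by
#' `1 + coupling * r(t)`, where `r` is the supplied regressor rescaled to
#' `[0, 1]` — so a source's band-limited-power envelope is associated with
#' the regressor with strength proportional to its coupling, enabling
#' planted-effect recovery tests. An optional toy leadfield (inverse-distance
#' gains to a montage) is attached when a montage is given.
#'
#' @param n_sources number of sources (arranged on a near-square grid).
#' @param bands per-source band label in
#'   `c("delta","theta","alpha","beta","broadband")`; recycled.
#' @param coupling per-source association strength (>= 0); recycled.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param seed integer seed.
#' @param regressor optional per-sample series the envelopes couple to;
#'   required if any coupling is nonzero.
#' @param montage optional [montage] used to build a toy leadfield.
#' @return An object of class `source_scene`: positions (S x 3), an
#'   `igraph` `neighbor_graph`, `series` (S x T), `band_assignment`,
#'   `coupling`, `fs`, and optionally `leadfield` (C x S).
#' @export
simulate_source_scene <- function(n_sources, bands = "broadband",
                                  coupling = 0, fs = 250, duration_s = 10,
                                  seed = 1L, regressor = NULL,
                                  montage = NULL) {
  n_sources <- as.integer(n_sources)
  if (n_sources < 1L) stop_invalid("n_sources must be positive")
  bands <- rep_len(as.character(bands), n_sources)
  bad <- setdiff(unique(bands), .band_table()$name)
  if (length(bad))
    stop_invalid("unknown band label(s): ", paste(bad, collapse = ", "))
  coupling <- rep_len(as.numeric(coupling), n_sources)
  n <- floor(duration_s * fs)
  if (any(coupling != 0)) {
    if (is.null(regressor))
      stop_invalid("a regressor is required when coupling is nonzero")
    if (length(regressor) != n)
      stop_invalid("regressor length must equal duration_s * fs")
    rng <- range(regressor)
    r01 <- if (diff(rng) > 0) (regressor - rng[1]) / diff(rng) else regressor * 0
  } else r01 <- numeric(n)

  nc <- ceiling(sqrt(n_sources))
  nr <- ceiling(n_sources / nc)
  ix <- seq_len(n_sources) - 1L
  positions <- cbind(x = (ix %% nc) * 1.0, y = (ix %/% nc) * 1.0, z = 0)
  g <- igraph::make_lattice(c(nc, nr))
  g <- igraph::induced_subgraph(g, seq_len(n_sources))

  btab <- .band_table()
  series <- with_seed(seed, {
    out <- matrix(0, n_sources, n)
    for (s in seq_len(n_sources)) {
      x <- rnorm(n)
      b <- btab[btab$name == bands[s], ]
      if (!is.na(b$lo)) {
        bf <- signal::butter(3, c(b$lo, b$hi) / (fs / 2), type = "pass")
        x <- signal::filtfilt(bf, x)
      }
      out[s, ] <- x * (1 + coupling[s] * r01)
    }
    out
  })
  leadfield <- NULL
  if (!is.null(montage)) {
    ep <- montage$positions[, 1:2, drop = FALSE]
    sp <- positions[, 1:2, drop = FALSE]
    d2 <- outer(rowSums(ep^2), rowSums(sp^2), "+") - 2 * ep %*% t(sp)
    leadfield <- 1 / (1 + sqrt(pmax(d2, 0)))
  }
  structure(list(positions = positions, neighbor_graph = g, series = series,
                 band_assignment = bands, coupling = coupling, fs = fs,
                 leadfield = leadfield, seed = as.integer(seed)),
            class = "source_scene")
}
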