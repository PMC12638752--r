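# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's internal code paths: loops instead of
# matrix algebra, direct textbook definitions instead of shared helpers.

# Zero-mean unit-norm topography from a raw vector.
unit_map <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

# A pair (or set) of mutually orthogonal zero-mean unit maps on C channels.
orthogonal_maps <- function(k, C, seed = 42) {
  set.seed(seed)
  raw <- matrix(rnorm(k * C), k, C)
  raw <- raw - rowMeans(raw)
  q <- qr.Q(qr(t(raw)))[, seq_len(k), drop = FALSE]
  out <- t(q)
  out <- out - rowMeans(out)
  t(apply(out, 1, function(r) r / sqrt(sum(r^2))))
}

# Tiny recording straight from a data matrix.
rec_from_matrix <- function(X, fs = 250) {
  recording(X, fs, generate_montage(nrow(X)))
}

# Brute-force two-sample KS statistic: supremum of |ECDF difference|.
ks_stat_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  mx <- 0
  for (g in grid) {
    d <- abs(mean(x <= g) - mean(y <= g))
    if (d > mx) mx <- d
  }
  mx
}

# Brute-force TFCE: per-node threshold sweep with BFS connected components,
# mirroring the integral sum_h extent(h)^E * h^H * dh (midpoint thresholds).
tfce_brute <- function(stat, adj, e_exp = 0.5, h_exp = 2, n_steps = 100) {
  n <- length(stat)
  side <- function(v) {
    hmax <- max(v)
    out <- numeric(n)
    if (hmax <= 0) return(out)
    dh <- hmax / n_steps
    hs <- seq(dh / 2, hmax, by = dh)
    for (h in hs) {
      sup <- which(v >= h)
      visited <- rep(FALSE, n)
      for (s in sup) {
        if (visited[s]) next
        comp <- s
        queue <- s
        visited[s] <- TRUE
        while (length(queue)) {
          cur <- queue[1]; queue <- queue[-1]
          nb <- which(adj[cur, ] != 0)
          nb <- nb[nb %in% sup & !visited[nb]]
          visited[nb] <- TRUE
          comp <- c(comp, nb)
          queue <- c(queue, nb)
        }
        out[comp] <- out[comp] + length(comp)^e_exp * h^h_exp * dh
      }
    }
    out
  }
  side(pmax(stat, 0)) - side(pmax(-stat, 0))
}

# Run-length oracle for microstate durations with the halfway-boundary
# convention: interior run of L samples spans L/fs, edge runs are measured
# from the recording edge to the halfway boundary (also L/fs).
run_durations_brute <- function(labels, fs) {
  out <- data.frame(class = integer(0), duration_s = numeric(0))
  i <- 1
  n <- length(labels)
  while (i <= n) {
    if (is.na(labels[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(labels[j + 1]) && labels[j + 1] == labels[i]) j <- j + 1
    # halfway between sample centers ((i-1)-0.5)/fs and (i-0.5)/fs = (i-1)/fs
    start_t <- if (i == 1) 0 else (i - 1) / fs
    end_t <- if (j == n) n / fs else j / fs
    out <- rbind(out, data.frame(class = labels[i],
                                 duration_s = end_t - start_t))
    i <- j + 1
  }
  out
}

# Enumerate all assignments of P points into exactly K labelled non-empty
# clusters (up to label permutation we just take the max, so labelling
# duplicates are harmless) and return the best achievable totGEV with the
# first-principal-component template rule.
best_partition_gev <- function(U, w, K) {
  P <- nrow(U)
  best <- -Inf
  counter <- rep(1L, P)
  template_gev <- function(a) {
    tot <- 0
    for (k in unique(a)) {
      idx <- which(a == k)
      M <- U[idx, , drop = FALSE]
      ev <- eigen(crossprod(M), symmetric = TRUE)
      tpl <- ev$vectors[, 1]
      tpl <- tpl - mean(tpl)
      tpl <- tpl / sqrt(sum(tpl^2))
      tot <- tot + sum(w[idx] * (M %*% tpl)^2)
    }
    tot / sum(w)
  }
  # iterate over K^P label vectors, keep those using all K labels
  repeat {
    if (length(unique(counter)) == K) {
      g <- template_gev(counter)
      if (g > best) best <- g
    }
    j <- P
    while (j >= 1 && counter[j] == K) { counter[j] <- 1L; j <- j - 1L }
    if (j == 0) break
    counter[j] <- counter[j] + 1L
  }
  best
}
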