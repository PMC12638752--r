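#' @keywords internal
"_PACKAGE"

#' @importFrom stats rgamma rnorm runif sd median cor ks.test fft
#' @importFrom tools file_ext
#' @importFrom utils head tail read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the global RNG stream untouched semantics-wise
# (code consumes from the current stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and one or more indices,
# kept below 2^31 so set.seed() accepts it.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 12345 + 1) %% 2147483647
  as.integer(s)
}

stop_invalid <- function(...) {
  stop(structure(class = c("ratstates_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Remove the per-row mean and scale each row of a maps matrix (rows =
# topographies, columns = channels) to unit L2 norm. Zero rows stay zero.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  nz <- nrm > 0
  maps[nz, ] <- maps[nz, , drop = FALSE] / nrm[nz]
  maps
}

# Deterministic sign convention: the entry of largest magnitude is positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

# First principal spatial component of a set of topographies (rows),
# the polarity-invariant "mean map" used as a cluster template.
principal_map <- function(maps) {
  if (nrow(maps) == 1L) return(fix_sign(normalize_maps(maps)[1L, ]))
  cp <- crossprod(maps)
  v <- eigen(cp, symmetric = TRUE)$vectors[, 1L]
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  fix_sign(v / n)
}
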