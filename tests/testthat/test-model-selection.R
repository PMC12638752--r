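test_that("dispersion is zero for singletons and hand-computable for pairs", {
  set.seed(15)
  peaks <- matrix(rnorm(6 * 19), 6)
  expect_equal(cluster_dispersion(peaks, 1:6), 0)
  M <- orthogonal_maps(2, 19, seed = 16)
  # one cluster holding two orthogonal unit maps: d = 1 - |r| = 1,
  # W = n * mean pairwise d^2 = 2 * 1
  expect_equal(cluster_dispersion(M, c(1, 1)), 2, tolerance = 1e-9)
})

test_that("well-separated planted clusters collapse the dispersion", {
  M <- orthogonal_maps(3, 19, seed = 17)
  set.seed(18)
  idx <- rep(1:3, each = 30)
  peaks <- M[idx, ] + matrix(rnorm(90 * 19, sd = 0.05), 90)
  fit <- aahc_cluster(peaks, rep(1, 90), 2, 5)
  W2 <- cluster_dispersion(peaks, fit$models[["2"]]$assignments)
  W3 <- cluster_dispersion(peaks, fit$models[["3"]]$assignments)
  expect_lt(W3, W2 / 5)
})

test_that("KL finds a constructed elbow and is flat without one", {
  m <- 19
  kv <- 2:8
  # exact elbow at K = 3: scaled dispersion K^(2/m) W(K) drops then stalls
  g <- function(K) ifelse(K < 3, 10 - 4 * (K - 2), 2 - 0.1 * (K - 3))
  W <- g(kv) / kv^(2 / m)
  kl <- kl_criterion(W, kv, m)
  expect_equal(kl$chosen_k, 3L)
  # linear decay of the scaled dispersion: no pronounced maximum
  W_lin <- (20 - kv) / kv^(2 / m)
  kl_lin <- kl_criterion(W_lin, kv, m)
  s <- kl_lin$scores[!is.na(kl_lin$scores)]
  expect_true(all(abs(s - 1) < 1e-9))
  expect_error(kl_criterion(c(1, 2), 2:3, m),
               class = "ratstates_invalid_argument")
})

test_that("CV is zero at a perfect fit and penalised near K = C-1", {
  M <- orthogonal_maps(2, 8, seed = 19)
  peaks <- M[rep(1:2, 20), ]
  fit <- aahc_cluster(peaks, rep(1, 40), 2, 2)
  cv <- cv_criterion(peaks, fit)
  expect_equal(unname(cv$scores["2"]), 0, tolerance = 1e-12)
  # penalty factor at the boundary: sigma2 * ((C-1)/(C-1-K))^2 with C = 8,
  # K = 5 gives (7/2)^2 = 12.25 times sigma2
  M5 <- orthogonal_maps(5, 8, seed = 20)
  set.seed(21)
  pk5 <- M5[rep(1:5, 12), ] + matrix(rnorm(60 * 8, sd = 0.01), 60)
  fit5 <- aahc_cluster(pk5, rep(1, 60), 5, 5)
  mod <- fit5$models[["5"]]
  X <- pk5 - rowMeans(pk5)
  proj <- rowSums(X * mod$maps[mod$assignments, ])
  sigma2 <- sum(rowSums(X^2) - proj^2) / (60 * 7)
  expect_equal(unname(cv_criterion(pk5, fit5)$scores["5"]),
               sigma2 * (7 / 2)^2, tolerance = 1e-12)
  expect_error(cv_criterion(peaks, aahc_cluster(peaks, rep(1, 40), 7, 7)),
               class = "ratstates_invalid_argument")
})

test_that("auxiliary criteria behave in the separation and overlap limits", {
  M <- orthogonal_maps(3, 19, seed = 22)
  set.seed(23)
  idx <- rep(1:3, each = 20)
  peaks <- M[idx, ] + matrix(rnorm(60 * 19, sd = 0.03), 60)
  fit <- aahc_cluster(peaks, rep(1, 60), 2, 6)
  aux <- auxiliary_criteria(peaks, fit)
  # tight well-separated clusters: DB small at the true K and argmin there
  expect_equal(unname(aux$chosen_k["db"]), 3L)
  expect_lt(aux$db[["3"]], 0.2)
  expect_gt(aux$dunn[["3"]], aux$dunn[["6"]])
})

test_that("the metacriterion is a lower-median vote", {
  expect_equal(metacriterion_select(c(kl = 5, cv = 5, db = 4)), 5L)
  expect_equal(metacriterion_select(c(kl = 4, cv = 6)), 4L)
  expect_error(metacriterion_select(c(kl = NA)),
               class = "ratstates_invalid_argument")
})

test_that("criteria are invariant to channel permutation and sign flip", {
  rec <- simulate_dataset(duration_s = 15, seed = 24)
  X <- average_reference(rec)$data
  gfp <- compute_gfp(rec)
  pk <- gfp$peak_indices
  peaks <- t(X[, pk])
  perm <- sample(ncol(peaks))
  variants <- list(peaks, -peaks, peaks[, perm])
  tabs <- lapply(variants, function(P) {
    fit <- aahc_cluster(P, gfp$values[pk], 2, 6)
    ct <- criterion_table(P, fit)
    ct$dunn <- NULL  # Dunn's point-pair min is tie-sensitive; checked above
    ct
  })
  expect_equal(tabs[[1]], tabs[[2]], tolerance = 1e-8)
  expect_equal(tabs[[1]], tabs[[3]], tolerance = 1e-8)
})

test_that("KL recovers the planted K = 5 on study-like synthetic data", {
  hits <- 0L
  n_runs <- 5L
  for (s in seq_len(n_runs)) {
    rec <- simulate_dataset(duration_s = 60, seed = 300 + s)
    fit <- fit_microstates(rec, k_min = 1, k_max = 10)
    gfp <- attr(fit, "gfp")
    peaks <- t(average_reference(rec)$data[, gfp$peak_indices])
    W <- vapply(fit$k_values, function(K)
      cluster_dispersion(peaks, fit$models[[as.character(K)]]$assignments), 0)
    kl <- kl_criterion(W, fit$k_values, 19)
    if (kl$chosen_k == 5L) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
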