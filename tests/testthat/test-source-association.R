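test_that("band definitions carry the documented edges", {
  b <- eeg_bands()
  expect_equal(b$lo[b$name == "delta"], 2)
  expect_equal(b$hi[b$name == "delta"], 4)
  expect_equal(b[b$name == "alpha", c("lo", "hi")],
               data.frame(lo = 8, hi = 12), ignore_attr = TRUE)
  expect_equal(b$hi[b$name == "beta"], 20)
})

test_that("the Hilbert envelope recovers the amplitude of an in-band tone", {
  fs <- 250
  t <- (0:(8 * fs - 1)) / fs
  x <- 1.7 * sin(2 * pi * 10 * t)
  env_a <- band_envelope(x, "alpha", fs)
  mid <- (2 * fs):(6 * fs)
  expect_lt(max(abs(env_a[mid] - 1.7)) / 1.7, 0.02)
  env_bb <- band_envelope(x, "broadband", fs)
  expect_lt(max(abs(env_bb[mid] - 1.7)) / 1.7, 0.02)
  # out-of-band: the delta filter crushes a 10 Hz tone
  env_d <- band_envelope(x, "delta", fs)
  expect_lt(max(env_d[mid]), 0.05 * 1.7)
  expect_error(band_envelope(x, "gamma", fs),
               class = "ratstates_invalid_argument")
  expect_error(band_envelope(x, list(lo = 100, hi = 130), fs),
               class = "ratstates_invalid_argument")
})

test_that("GMD hits its algebraic landmarks", {
  set.seed(32)
  u <- unit_map(rnorm(19))
  w <- rnorm(19); w <- w - mean(w)
  v <- unit_map(w - sum(w * u) * u)      # orthogonal to u
  rec <- rec_from_matrix(cbind(u, u, -u, v))
  gmd <- compute_gmd(rec)
  expect_true(is.na(gmd[1]))
  expect_equal(gmd[2], 0, tolerance = 1e-12)
  expect_equal(gmd[3], 2, tolerance = 1e-12)
  expect_equal(gmd[4], sqrt(2), tolerance = 1e-12)
})

test_that("microstate regressors are absolute template projections", {
  M <- orthogonal_maps(3, 19, seed = 33)
  model <- structure(list(maps = M, k = 3L), class = "microstate_model")
  rec <- rec_from_matrix(cbind(M[2, ], -3 * M[2, ], M[1, ] + 2 * M[3, ]))
  regs <- build_regressors(rec, model)
  expect_equal(regs$b[1, ], c(MS1 = 0, MS2 = 1, MS3 = 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(regs$b[2, 2], 3, tolerance = 1e-9)
  expect_equal(regs$b[3, ], c(1, 0, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # polarity invariance of the whole regressor set
  regs_neg <- build_regressors(rec_from_matrix(-rec$data), model)
  expect_equal(regs$b, regs_neg$b, tolerance = 1e-12)
})

test_that("the source GLM recovers planted coefficients", {
  rec <- simulate_dataset(duration_s = 10, seed = 34)
  model <- fit_microstates(rec, 3, 3)$models[["3"]]
  regs <- build_regressors(average_reference(rec), model)
  n <- length(regs$gfp)
  set.seed(35)
  blp <- 0.5 * regs$b[, 2] + rnorm(n, sd = 1e-8)
  g <- fit_source_glm(blp, regs, 2)
  expect_equal(g$beta1, 0.5, tolerance = 1e-4)
  # nuisance absorbs a GFP-shaped envelope
  g2 <- fit_source_glm(regs$gfp, regs, 2)
  expect_equal(g2$beta1, 0, tolerance = 1e-9)
  expect_equal(unname(g2$coefficients["gfp", 1]), 1, tolerance = 1e-9)
  # independent envelopes give near-zero mean beta1 across sources
  blp_null <- matrix(abs(rnorm(200 * n)), 200)
  g3 <- fit_source_glm(blp_null, regs, 1)
  se <- sd(g3$beta1) / sqrt(200)
  expect_lt(abs(mean(g3$beta1)), 2 * se + 1e-6)
  # rank-deficient design is flagged
  regs_bad <- regs
  regs_bad$gmd <- regs_bad$gfp
  expect_warning(gb <- fit_source_glm(blp, regs_bad, 2), "rank")
  expect_true(gb$rank_deficient)
})

test_that("TFCE matches its closed form on a single active node", {
  g <- igraph::make_ring(5)
  stat <- c(0, 0, 2, 0, 0)
  enh <- tfce_enhance(stat, g, e_exp = 0.5, h_exp = 2, dh = 2 / 1000)
  expect_equal(enh[3], 2^3 / 3, tolerance = 1e-2)
  expect_equal(enh[-3], rep(0, 4))
  expect_equal(tfce_enhance(rep(0, 5), g), rep(0, 5))
})

test_that("TFCE equals brute-force threshold integration on small graphs", {
  set.seed(36)
  for (i in 1:4) {
    n <- sample(8:20, 1)
    adj <- matrix(0, n, n)
    edges <- which(upper.tri(adj), arr.ind = TRUE)
    pick <- edges[runif(nrow(edges)) < 0.2, , drop = FALSE]
    adj[pick] <- 1
    adj <- adj + t(adj)
    stat <- rnorm(n)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(tfce_enhance(stat, g, n_steps = 50),
                 tfce_brute(stat, adj, n_steps = 50), tolerance = 1e-9)
  }
})

test_that("TFCE is monotone under upscaling and odd under negation", {
  set.seed(37)
  g <- igraph::make_lattice(c(4, 4))
  stat <- rnorm(16)
  e1 <- tfce_enhance(stat, g)
  e2 <- tfce_enhance(3 * stat, g)
  expect_true(all(e2 * sign(stat) >= e1 * sign(stat) - 1e-12))
  expect_equal(tfce_enhance(-stat, g), -e1, tolerance = 1e-12)
})

test_that("group permutation testing recovers a planted cluster", {
  set.seed(38)
  n_src <- 100
  g <- igraph::make_lattice(c(10, 10))
  planted <- c(34, 35, 44, 45, 54)
  beta <- matrix(rnorm(10 * n_src, sd = 0.02), 10, n_src)
  beta[, planted] <- beta[, planted] + 0.1
  sm <- group_permutation_test(beta, g, alpha = 0.01, n_perm = 500,
                               seed = 39)
  expect_true(all(sm$signif_mask[planted]))
  expect_lt(sum(sm$signif_mask[-planted]), 5)
  # negating all subject maps mirrors the effect and the mask
  sm_neg <- group_permutation_test(-beta, g, alpha = 0.01, n_perm = 500,
                                   seed = 39)
  expect_equal(sm_neg$beta1, -sm$beta1)
  expect_identical(sm_neg$signif_mask, sm$signif_mask)
  expect_error(group_permutation_test(beta[1:4, ], g),
               class = "ratstates_too_few_subjects")
})

test_that("stat-map summaries report fractions and masked correlations", {
  mk <- function(enh, mask) structure(list(enhanced = enh, p = mask * 0,
                                           signif_mask = mask),
                                      class = "stat_map")
  set.seed(40)
  n <- 12
  e1 <- abs(rnorm(n)); m1 <- e1 > 0.5
  e2 <- abs(rnorm(n)); m2 <- e2 > 0.8
  empty <- mk(rep(0, n), rep(FALSE, n))
  s <- summarize_statmaps(list(a = mk(e1, m1), b = mk(e2, m2),
                               none = empty))
  expect_equal(s$fractions[["a"]], mean(m1))
  expect_equal(s$fractions[["none"]], 0)
  expect_false("none" %in% rownames(s$correlations))
  expect_equal(s$correlations["a", "a"], 1)
  # brute-force pairwise value on the union support
  supp <- m1 | m2
  v1 <- ifelse(m1, e1, 0)[supp]
  v2 <- ifelse(m2, e2, 0)[supp]
  expect_equal(s$correlations["a", "b"], cor(v1, v2), tolerance = 1e-12)
})

test_that("three-orientation series reduce to their principal component", {
  set.seed(41)
  base <- sin(2 * pi * 5 * (0:999) / 250)
  xyz <- rbind(2 * base, -base, 0.5 * base) +
    matrix(rnorm(3000, sd = 0.01), 3)
  pc <- pc_reduce(xyz)
  expect_gt(abs(cor(pc, base)), 0.999)
})
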