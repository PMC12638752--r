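make_model <- function(maps) {
  structure(list(maps = maps, k = nrow(maps), training_gev = NA,
                 provenance = list()), class = "microstate_model")
}

test_that("backfitting assigns by absolute spatial correlation", {
  M <- orthogonal_maps(4, 19, seed = 9)
  model <- make_model(M)
  rec <- rec_from_matrix(t(rbind(2.5 * M[3, ], -M[3, ], 0.1 * M[1, ])))
  lab <- backfit(rec, model)
  expect_identical(lab$labels, c(3L, 3L, 1L))
  expect_equal(lab$correlations, c(1, 1, 1), tolerance = 1e-9)
  # zero-GFP sample is unassigned
  rec0 <- rec_from_matrix(cbind(M[2, ], rep(0, 19)))
  lab0 <- backfit(rec0, model)
  expect_identical(lab0$labels, c(2L, NA))
})

test_that("GEV is 1 for a perfect fit and 0 for orthogonal labelling", {
  M <- orthogonal_maps(3, 19, seed = 10)
  t_s <- (0:499) / 250
  env <- abs(sin(2 * pi * 10 * t_s)) + 0.05
  rec <- rec_from_matrix(outer(M[1, ], env))
  gev <- compute_gev(rec, make_model(M))
  expect_equal(gev$tot_gev, 1, tolerance = 1e-9)
  expect_equal(gev$gev_k[1], 1, tolerance = 1e-9)
  expect_equal(gev$gev_k[2:3], c(0, 0))
  expect_equal(gev$tot_gev, sum(gev$gev_k))

  # labels forced onto maps orthogonal to every sample -> totGEV = 0
  forced <- structure(list(labels = rep(2L, 500),
                           correlations = as.numeric(abs(M[2, ] %*% M[1, ])) *
                             rep(1, 500),
                           k = 3L, fs = 250), class = "label_sequence")
  gev0 <- compute_gev(rec, make_model(M), forced)
  expect_lt(gev0$tot_gev, 1e-18)
})

test_that("structured recordings explain far more variance than noise", {
  rec <- simulate_dataset(duration_s = 30, seed = 12)
  fitS <- fit_microstates(rec, 5, 5)
  gev_struct <- fitS$models[["5"]]$training_gev
  set.seed(13)
  noise <- rec_from_matrix(matrix(rnorm(19 * 250 * 30), 19), 250)
  fitN <- fit_microstates(noise, 5, 5)
  expect_gte(gev_struct - fitN$models[["5"]]$training_gev, 0.2)
})

test_that("durations follow the halfway-boundary convention", {
  labels <- rep(c(1L, 2L), each = 3)
  stats <- microstate_parameters(labels, gfp = rep(1, 6), fs = 250)
  expect_equal(stats$duration_s, c(3, 3) / 250)
  expect_equal(stats$duration_ms, c(12, 12))
  expect_equal(stats$n_runs, c(1, 1))
  oracle <- run_durations_brute(labels, 250)
  expect_equal(stats$duration_s,
               tapply(oracle$duration_s, oracle$class, mean),
               ignore_attr = TRUE)
})

test_that("single-class sequences have coverage 1 and occurrence 1/duration", {
  stats <- microstate_parameters(rep(1L, 500), rep(1, 500), fs = 250)
  expect_equal(stats$coverage, 1)
  expect_equal(stats$occurrence_per_s, 1 / 2)   # one run in 2 s
})

test_that("conservation identities hold on random label sequences", {
  set.seed(14)
  for (rep_i in 1:5) {
    k <- sample(2:6, 1)
    labels <- simulate_state_sequence(
      ground_truth(k, generate_montage(19), seed = rep_i), 20, 250,
      seed = 50 + rep_i)
    gfp <- runif(length(labels), 0.1, 2)
    st <- microstate_parameters(labels, gfp, fs = 250)
    expect_equal(sum(st$coverage), 1, tolerance = 1e-9)
    # coverage = occurrence x mean duration within one sample period per run
    pred <- st$occurrence_per_s * st$duration_s
    expect_true(all(abs(st$coverage - pred) <=
                      st$n_runs / (250 * attr(st, "total_s")) + 1e-12))
  }
})

test_that("expected transition formula matches hand evaluation", {
  # Occ = (2, 4, 6), MeanOcc = 4: ExpTM(1,2) = (0.5 * 1) / (1 - 0.5) = 1
  occ <- c(2, 4, 6)
  expect_warning(E <- expected_transitions(occ), "singular")
  expect_equal(E[1, 2], 1.0)
  expect_equal(E[1, 3], (0.5 * 1.5) / 0.5)
  expect_true(all(is.infinite(E[2, c(1, 3)])))   # Occ(2) = MeanOcc
  expect_equal(diag(E), c(0, 0, 0))
  # absent class contributes nothing in either direction (Occ(2) sits at
  # the mean here, so the singular-row warning is expected)
  E0 <- suppressWarnings(expected_transitions(c(0, 2, 4)))
  expect_equal(E0[1, ], c(0, 0, 0))
  expect_equal(E0[2:3, 1], c(0, 0))
})

test_that("observed transitions of an alternating sequence are deterministic", {
  labels <- rep(c(1L, 2L), times = 10)
  # both classes occur at exactly the mean rate, so the expected-transition
  # formula is singular here; the observed matrix is what is under test
  ta <- suppressWarnings(transition_analysis(labels, fs = 250, k = 2))
  expect_equal(ta$observed, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(diag(ta$observed), c(0, 0))
  expect_equal(rowSums(ta$observed), c(1, 1))
})
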