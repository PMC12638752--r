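test_that("built-in montages have the expected unique label sets", {
  m19 <- generate_montage(19)
  expect_length(unique(m19$channel_names), 19L)
  m21 <- generate_montage(21)
  expect_length(unique(m21$channel_names), 21L)
  expect_setequal(setdiff(m21$channel_names, m19$channel_names),
                  c("Fpz", "Oz"))
  m2 <- generate_montage(2)
  expect_length(m2$channel_names, 2L)
  expect_false(identical(m2$positions[1, ], m2$positions[2, ]))
  expect_error(generate_montage(0), class = "ratstates_invalid_argument")
  expect_error(generate_montage(-3), class = "ratstates_invalid_argument")
})

test_that("state sequences are semi-Markov with the requested dwell structure", {
  mont <- generate_montage(19)
  t1 <- ground_truth(1, mont, seed = 5)
  expect_true(all(simulate_state_sequence(t1, 2, 250) == 1L))

  t5 <- ground_truth(5, mont, mean_dwell_s = 0.1, seed = 7)
  a <- simulate_state_sequence(t5, 30, 250, seed = 11)
  b <- simulate_state_sequence(t5, 30, 250, seed = 11)
  expect_identical(a, b)

  long <- simulate_state_sequence(t5, 120, 250, seed = 13)
  r <- rle(long)
  mean_dwell <- mean(r$lengths) / 250
  expect_lt(abs(mean_dwell - 0.1) / 0.1, 0.10)

  bad <- ground_truth(3, mont, seed = 1)
  bad$transition_matrix[2, ] <- 0
  expect_error(simulate_state_sequence(bad, 1, 250),
               class = "ratstates_invalid_argument")
})

test_that("noiseless recordings reproduce planted maps at every GFP peak", {
  truth <- ground_truth(5, generate_montage(19), noise_sd = 0, seed = 3)
  labels <- simulate_state_sequence(truth, 10, 250, seed = 4)
  rec <- simulate_recording(truth, labels, 250)
  gfp <- compute_gfp(rec)
  for (p in gfp$peak_indices) {
    r <- spatial_correlation(rec$data[, p], truth$maps[labels[p], ])
    expect_equal(r, 1, tolerance = 1e-9)
  }
  # perfect-fit limit: totGEV of the true maps equals 1
  model <- structure(list(maps = truth$maps, k = 5L, training_gev = NA,
                          provenance = list()), class = "microstate_model")
  gev <- compute_gev(rec, model)
  expect_equal(gev$tot_gev, 1, tolerance = 1e-9)
  # backfitting the true maps reproduces the planted labels at peaks
  lab <- backfit(rec, model)
  expect_identical(lab$labels[gfp$peak_indices], labels[gfp$peak_indices])
})

test_that("recordings are reproducible and respect the SNR request", {
  r1 <- simulate_dataset(duration_s = 5, seed = 99)
  r2 <- simulate_dataset(duration_s = 5, seed = 99)
  expect_identical(r1$data, r2$data)
  # channel means vanish per sample by construction
  expect_lt(max(abs(colMeans(r1$data))), 1e-12)
})

test_that("planted coverage approaches the stationary distribution", {
  truth <- ground_truth(5, generate_montage(19), seed = 21)
  labels <- simulate_state_sequence(truth, 600, 250, seed = 22)
  cov_emp <- tabulate(labels, 5) / length(labels)
  expect_true(all(abs(cov_emp - stationary_coverage(truth)) < 0.10))
})

test_that("source scenes are deterministic and validate band labels", {
  s1 <- simulate_source_scene(12, bands = "alpha", fs = 250,
                              duration_s = 2, seed = 8)
  s2 <- simulate_source_scene(12, bands = "alpha", fs = 250,
                              duration_s = 2, seed = 8)
  expect_identical(s1$series, s2$series)
  expect_true(igraph::is_igraph(s1$neighbor_graph))
  adj <- as.matrix(igraph::as_adjacency_matrix(s1$neighbor_graph))
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj) == 0))
  expect_error(simulate_source_scene(4, bands = "gamma", seed = 1),
               class = "ratstates_invalid_argument")
  expect_error(simulate_source_scene(4, coupling = 1, seed = 1),
               class = "ratstates_invalid_argument")
})
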