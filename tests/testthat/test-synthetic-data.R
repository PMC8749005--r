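test_that("planted latent arc lengths scale exactly with the factors", {
  cfg <- small_config()
  # E = 1, shrink = 1: both conditions trace the same loop
  truth <- small_truth(expansion_factor = 1, accuracy_shrink = 1,
                       noise_sd = 0)
  sim <- simulate_session(cfg, truth, seed = 4)
  lens <- sim$latent_lengths
  expect_equal(unname(lens[["2back.correct"]] / lens[["1back.correct"]]),
               1, tolerance = 1e-3)
  # arbitrary factor: latent length ratio is exactly E
  truth2 <- small_truth(expansion_factor = 2.5, noise_sd = 0)
  sim2 <- simulate_session(cfg, truth2, seed = 4)
  l2 <- sim2$latent_lengths
  expect_equal(unname(l2[["2back.correct"]] / l2[["1back.correct"]]),
               2.5, tolerance = 1e-3)
})

test_that("noiseless signals recover the loading matrix exactly", {
  cfg <- small_config()
  truth <- small_truth(expansion_factor = 1.5, noise_sd = 0)
  sim <- simulate_session(cfg, truth, seed = 5)
  # regress region signals on the HRF-convolved latent courses
  W_hat <- t(qr.coef(qr(sim$latent_tr), t(sim$ts)))
  expect_lt(sqrt(mean((W_hat - truth$loading_matrix)^2)), 1e-6)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config()
  truth <- small_truth(expansion_factor = 1.3, noise_sd = 0.05)
  a <- simulate_session(cfg, truth, seed = 9)
  b <- simulate_session(cfg, truth, seed = 9)
  expect_identical(a$ts, b$ts)
  expect_false(identical(a$ts, simulate_session(cfg, truth, seed = 10)$ts))
})

test_that("degenerate truth parameters are rejected", {
  expect_error(ground_truth(expansion_factor = 0), "expansion_factor")
  expect_error(ground_truth(ar1_coef = 1), "ar1_coef")
  expect_error(ground_truth(noise_sd = -1), "noise_sd")
  expect_error(ground_truth(n_regions = 2, latent_dim = 3), "n_regions")
})

test_that("noise calibration hits the requested trial-level SNR", {
  cfg <- small_config()
  truth <- small_truth(expansion_factor = 1.5, target_snr = 2,
                       snr_reference = "participant")
  sched <- label_accuracy(generate_schedule(cfg), 1)
  sd_cal <- calibrate_noise_sd(sched, truth, target_snr = 2, seed = 1)
  # empirical check: refit with that noise level and measure the ratio
  truth$noise_sd <- sd_cal
  sim <- simulate_session(cfg, truth, schedule = sched, seed = 6)
  basis <- hrf_basis()
  design <- build_design_matrix(sched, basis, n_scans = sim$n_scans)
  noisy <- fit_trial_responses(sim$ts, design)
  clean <- fit_trial_responses(sim$clean, design)
  snr_emp <- sqrt(mean(clean$values^2) / mean((noisy$values - clean$values)^2))
  expect_equal(snr_emp, 2, tolerance = 0.25)
})

test_that("toy manifolds carry their advertised ground truth", {
  # noiseless curve: constant-speed parameterization, equal steps
  cur <- make_toy_manifold("noisy_curve", n_points = 50, ambient_dim = 5,
                           noise_sd = 0, seed = 1)
  steps <- sqrt(rowSums(diff(cur$X)^2))
  expect_true(all(steps > 0))
  expect_lt(sd(steps) / mean(steps), 1e-3)

  # two_clusters: every point's nearest neighbor is in its own cluster
  tc <- make_toy_manifold("two_clusters", n_points = 60, ambient_dim = 6,
                          noise_sd = 0.05, seed = 2)
  D <- as.matrix(dist(tc$X))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  expect_true(all(tc$labels[nn] == tc$labels))

  # single gaussian blob: sample mean within 3 SE of the center
  gb <- make_toy_manifold("gaussian_blobs", n_points = 400,
                          ambient_dim = 4, noise_sd = 0.5, seed = 3,
                          n_blobs = 1)
  se <- 0.5 / sqrt(400)
  expect_true(all(abs(colMeans(gb$X) - gb$centers[1, ]) < 3 * se))

  expect_error(make_toy_manifold("spiral"), "arg")
  expect_error(make_toy_manifold("noisy_curve", n_points = 5), "n_points")
})
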