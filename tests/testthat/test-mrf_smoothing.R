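test_that("energy closed forms: uniform probabilities and homogeneous labels", {
  K <- 5; nx <- 6; ny <- 6
  p <- matrix(1 / K, nx * ny, K)
  probs <- probability_volume(p, array(TRUE, c(nx, ny, 1)), 1:K,
                              voxel_grid(c(nx, ny, 1)))
  lab <- habitat_map(array(1L, c(nx, ny, 1)), probs$grid)
  ## beta = 0: E = n log K for uniform probabilities, any labeling
  e0 <- labeling_energy(lab, probs, mrf_config(beta = 0))
  expect_equal(e0, nx * ny * log(K), tolerance = 1e-12)
  ## homogeneous labeling: pairwise term vanishes at any beta
  e2 <- labeling_energy(lab, probs, mrf_config(beta = 2))
  expect_equal(e2, e0, tolerance = 1e-12)
})

test_that("energy matches a hand-computed 2x2 toy", {
  ## probabilities per voxel (raster order), 2 classes
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7), c(0.2, 0.8))
  probs <- probability_volume(p, array(TRUE, c(2, 2, 1)), 1:2,
                              voxel_grid(c(2, 2, 1)))
  lab <- habitat_map(array(c(1L, 1L, 2L, 2L), c(2, 2, 1)), probs$grid)
  ## data term: -log .9 - log .6 - log .7 - log .8
  data_term <- -(log(0.9) + log(0.6) + log(0.7) + log(0.8))
  ## 2x2 slice, 8-neighborhood: pairs (1,2),(3,4) concordant; (1,3),(2,4),
  ## (1,4),(2,3) discordant -> 4 discordant pairs
  e <- labeling_energy(lab, probs, mrf_config(beta = 1.5))
  expect_equal(e, data_term + 1.5 * 4, tolerance = 1e-12)
})

test_that("beta = 0 ICM returns argmax labels and converges in one sweep", {
  probs <- random_prob_slice(seed = 71)
  res <- icm_denoise(probs, mrf_config(beta = 0))
  expect_identical(res$labels$labels, argmax_labels(probs)$labels)
  expect_equal(res$trace$changes, 0L)
  expect_true(res$trace$converged)
})

test_that("a single flipped voxel adopts the surrounding label", {
  nx <- 9; ny <- 9
  ## near-uniform probabilities, slight preference for class 2 at the center
  p <- matrix(rep(c(0.5, 0.5), each = nx * ny), nx * ny, 2)
  center <- 5 + (5 - 1) * nx
  p[, 1] <- 0.51; p[, 2] <- 0.49
  p[center, ] <- c(0.49, 0.51)
  probs <- probability_volume(p / rowSums(p), array(TRUE, c(nx, ny, 1)), 1:2,
                              voxel_grid(c(nx, ny, 1)))
  raw <- argmax_labels(probs)
  expect_equal(raw$labels[5, 5, 1], 2L)
  res <- icm_denoise(probs, mrf_config(beta = 1))
  expect_equal(res$labels$labels[5, 5, 1], 1L)  # 8 discordant pairs beat -log p gap
  expect_true(all(res$labels$labels == 1L))
})

test_that("energy is non-increasing across ICM sweeps", {
  for (s in 1:5) {
    probs <- random_prob_slice(seed = 700 + s)
    for (beta in c(0, 0.5, 1, 2)) {
      cfg <- mrf_config(beta = beta, max_iterations = 8)
      energies <- vapply(0:8, function(k) {
        lab <- if (k == 0) argmax_labels(probs)
               else icm_denoise(probs, mrf_config(beta = beta,
                                                  max_iterations = k))$labels
        labeling_energy(lab, probs, cfg)
      }, numeric(1))
      expect_true(all(diff(energies) <= 1e-9),
                  info = sprintf("seed %d beta %g", s, beta))
    }
  }
})

test_that("ICM terminates and reduces neighbor discordance on phantoms", {
  study <- generate_phantom(phantom_spec(shape = c(32, 32, 4), seed = 72,
    compartments = list(
      list(type = "ellipsoid", class_id = 1L, center = c(16, 16, 2),
           radii = c(13, 13, 1.8)),
      list(type = "ellipsoid", class_id = 3L, center = c(20, 14, 2),
           radii = c(5, 5, 1.2)))))
  field <- phantom_feature_field(study)
  tab <- phantom_training_rois(study, classes = c(1, 3), roi_side = 5,
                               n_per_class = 1, seed = 2)
  m <- fit_gaussian_nb(training_set(
    suppressWarnings(phantom_labeled_rois(study, tab))))
  pred <- classify_volume(m, field, study$voi)
  for (beta in c(0.5, 1, 2)) {
    res <- icm_denoise(pred$probs, mrf_config(beta = beta, max_iterations = 50))
    expect_true(res$trace$converged)
    expect_lte(res$trace$iterations, 50)
    expect_equal(res$trace$changes[res$trace$iterations], 0L)
    expect_lte(discordant_pairs(res$labels), discordant_pairs(pred$labels))
  }
})

test_that("ICM is deterministic for a fixed input", {
  probs <- random_prob_slice(nx = 12, ny = 12, seed = 73)
  r1 <- icm_denoise(probs, mrf_config(beta = 1))
  r2 <- icm_denoise(probs, mrf_config(beta = 1))
  expect_identical(r1$labels$labels, r2$labels$labels)
  expect_identical(r1$trace$changes, r2$trace$changes)
})

test_that("per-slice smoothing reports one trace per occupied slice", {
  study <- generate_phantom(phantom_spec(seed = 74))
  field <- phantom_feature_field(study)
  tab <- phantom_training_rois(study, seed = 3)
  m <- fit_gaussian_nb(training_set(phantom_labeled_rois(study, tab)))
  pred <- classify_volume(m, field, study$voi)
  sm <- smooth_study(pred$probs, study$voi, mrf_config(beta = 1))
  occupied <- sum(apply(study$voi$membership, 3, any))
  expect_length(sm$traces, occupied)
  expect_true(sm$all_converged)
  expect_true(is.finite(sm$median_iterations))
  expect_true(all(vapply(sm$traces,
                         function(t) t$changes[t$iterations] == 0L,
                         logical(1))))
  ## beta = 0 converges in one sweep on every slice
  sm0 <- smooth_study(pred$probs, study$voi, mrf_config(beta = 0))
  expect_true(all(vapply(sm0$traces, function(t) t$iterations, numeric(1)) == 1))

  ## single-slice VOI yields exactly one trace
  memb <- study$voi$membership
  memb[, , -8] <- FALSE
  one <- smooth_study(pred$probs, mask_volume(memb, study$spec$spacing),
                      mrf_config(beta = 1))
  expect_length(one$traces, 1)
})

test_that("MRF beats raw argmax under boundary-probability perturbation", {
  study <- generate_phantom(phantom_spec(seed = 75))
  field <- phantom_feature_field(study)
  tab <- phantom_training_rois(study, seed = 4)
  m <- fit_gaussian_nb(training_set(phantom_labeled_rois(study, tab)))
  pred <- classify_volume(m, field, study$voi)
  noisy <- perturb_probability_volume(pred$probs, fraction = 0.05, seed = 76)
  raw <- argmax_labels(noisy)
  sm <- smooth_study(noisy, study$voi, mrf_config(beta = 1))
  truth <- study$truth$labels
  sel <- !is.na(truth) & !is.na(raw$labels)
  acc_raw <- mean(raw$labels[sel] == truth[sel])
  acc_mrf <- mean(sm$labels$labels[sel] == truth[sel])
  expect_gte(acc_mrf, acc_raw)
})

test_that("configuration invariants are enforced", {
  expect_error(mrf_config(beta = -1))
  expect_error(mrf_config(max_iterations = 0))
  expect_error(mrf_config(epsilon = 0))
  expect_error(mrf_config(epsilon = 0.1))
  expect_error(mrf_config(neighborhood = "26"))
})
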