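test_that("Gaussian NB recovers class statistics", {
  set.seed(21)
  n <- 500
  df <- rbind(
    data.frame(roi_id = "a", patient_id = "p", class_id = 1,
               adc_n = rnorm(n, 0.1, 0.01), ef_n = rnorm(n, 0.5, 0.01),
               ff_n = rnorm(n, 0.5, 0.01)),
    data.frame(roi_id = "b", patient_id = "p", class_id = 2,
               adc_n = rnorm(n, 0.9, 0.01), ef_n = rnorm(n, 0.5, 0.01),
               ff_n = rnorm(n, 0.5, 0.01)))
  df[, 4:6] <- pmin(pmax(df[, 4:6], 0), 1)
  m <- fit_gaussian_nb(df)
  expect_lt(abs(m$mu["1", "adc_n"] - 0.1), 1e-3)
  expect_lt(abs(m$mu["2", "adc_n"] - 0.9), 1e-3)
})

test_that("variance floor replaces zero variance, priors are frequencies", {
  df <- data.frame(roi_id = "a", patient_id = "p",
                   class_id = rep(1:2, c(100, 300)),
                   adc_n = c(rep(0.5, 100), runif(300)),
                   ef_n = runif(400), ff_n = runif(400))
  m <- fit_gaussian_nb(df)
  expect_equal(unname(m$prior), c(0.25, 0.75))
  expect_equal(m$sigma2["1", "adc_n"], m$var_floor)  # constant feature
  expect_gt(m$var_floor, 0)

  expect_error(fit_gaussian_nb(df[c(1, 101:400), ]), "fewer than 2")
})

test_that("NB posterior degenerate and symmetric cases", {
  set.seed(22)
  one <- data.frame(roi_id = "a", patient_id = "p", class_id = 3,
                    adc_n = runif(50), ef_n = runif(50), ff_n = runif(50))
  m1 <- fit_gaussian_nb(one)
  p <- predict_proba(m1, matrix(runif(30), 10, 3))
  expect_true(all(p == 1))

  ## mirrored means, equal priors: the midpoint is exactly ambiguous
  n <- 100
  df <- data.frame(roi_id = rep(c("a", "b"), each = n), patient_id = "p",
                   class_id = rep(1:2, each = n),
                   adc_n = c(rnorm(n, 0.3, 0.02), rnorm(n, 0.7, 0.02)),
                   ef_n = 0.5, ff_n = 0.5)
  m2 <- fit_gaussian_nb(df)
  ## symmetrize the fitted model so the midpoint query is exact
  m2$mu[, "adc_n"] <- c(0.3, 0.7)
  m2$sigma2[, "adc_n"] <- 0.02^2
  m2$sigma2[, c("ef_n", "ff_n")] <- m2$var_floor
  m2$mu[, c("ef_n", "ff_n")] <- 0.5
  m2$prior <- c(0.5, 0.5)
  p_mid <- predict_proba(m2, matrix(c(0.5, 0.5, 0.5), 1, 3))
  expect_equal(as.numeric(p_mid), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("NB matches the brute-force Bayes oracle to 1e-9", {
  m <- fit_gaussian_nb(random_training_df(seed = 23))
  set.seed(24)
  x <- matrix(runif(600), 200, 3)
  p_pkg <- predict_proba(m, x)
  p_orc <- nb_oracle(m, x)
  expect_lt(max(abs(p_pkg - p_orc)), 1e-9)
  expect_equal(rowSums(p_pkg), rep(1, 200), tolerance = 1e-12)
})

test_that("NB posterior is invariant to consistent feature reordering", {
  df <- random_training_df(seed = 25)
  m <- fit_gaussian_nb(df)
  perm <- c(3, 1, 2)
  df_perm <- df
  df_perm[, c("adc_n", "ef_n", "ff_n")] <- df[, c("adc_n", "ef_n", "ff_n")][, perm]
  m_perm <- fit_gaussian_nb(df_perm)
  set.seed(26)
  x <- matrix(runif(60), 20, 3)
  expect_equal(predict_proba(m, x), predict_proba(m_perm, x[, perm]),
               tolerance = 1e-12)
})

test_that("Silverman bandwidth follows the rule-of-thumb formula", {
  set.seed(27)
  x <- matrix(rnorm(3000, 0.5, 0.2), 1000, 3)
  sigma_hat <- mean(apply(x, 2, sd))
  expected <- sigma_hat * (4 / ((3 + 2) * 1000))^(1 / (3 + 4))
  expect_equal(silverman_bandwidth(x), expected)

  ## doubling n at fixed spread shrinks h by 2^(-1/(d+4))
  x2 <- rbind(x, x)
  sigma_hat2 <- mean(apply(x2, 2, sd))
  expect_equal(silverman_bandwidth(x2),
               sigma_hat2 * (4 / (5 * 2000))^(1 / 7) , tolerance = 1e-12)
  expect_equal(silverman_bandwidth(x2) / silverman_bandwidth(x),
               (sigma_hat2 / sigma_hat) * 2^(-1 / 7), tolerance = 1e-10)

  ## zero-variance sample floors at 1e-4
  expect_equal(silverman_bandwidth(matrix(0.5, 10, 3)), 1e-4)
})

test_that("hyperparameter contracts are enforced per family", {
  set <- separable_training_set(seed = 28)
  expect_error(fit_classifier("NB", 1, set), "no hyperparameter")
  expect_error(fit_classifier("aKDE", 0.5, set), "no hyperparameter")
  expect_error(fit_classifier("kNN", NULL, set), "requires")
  expect_error(fit_classifier("kNN", 5, set), "outside")
  expect_error(fit_classifier("KDE", 20, set), "outside")
  expect_error(fit_classifier("bogus", 1, set))
})

test_that("kNN predicts nearest-neighbor vote fractions", {
  set <- separable_training_set(n_rois_per_class = 3, n_vox = 40, seed = 29)
  m <- fit_classifier("kNN", 34, set)
  q <- matrix(c(0.22, 0.5, 0.12), 1, 3)
  p <- predict_proba(m, q)
  ## independent vote count via explicit distance sort
  x <- as.matrix(set$data[, c("adc_n", "ef_n", "ff_n")])
  d <- sqrt(colSums((t(x) - as.numeric(q))^2))
  votes <- set$data$class_id[order(d)[1:34]]
  expected <- vapply(sort(unique(set$data$class_id)),
                     function(k) sum(votes == k) / 34, numeric(1))
  expect_equal(as.numeric(p), expected, tolerance = 1e-9)
})

test_that("kNN with k = n predicts empirical class frequencies everywhere", {
  set <- separable_training_set(n_rois_per_class = 2, n_vox = 30, seed = 30)
  n <- nrow(set$data)
  m <- fit_classifier("kNN", n, set)
  p <- predict_proba(m, matrix(runif(15), 5, 3))
  freq <- as.numeric(table(set$data$class_id)) / n
  for (i in 1:5) expect_equal(as.numeric(p[i, ]), freq, tolerance = 1e-9)
})

test_that("KDE uses the requested kernel bandwidth", {
  set <- separable_training_set(seed = 31)
  m <- fit_classifier("KDE", 0.75, set)
  expect_true(all(m$bandwidth == 0.75))
  q <- matrix(runif(30), 10, 3)
  p <- predict_proba(m, q)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)

  ## oracle: explicit kernel-sum density for one class at one point
  x1 <- m$by_class[[1]]
  q1 <- q[1, ]
  dens <- mean(exp(-rowSums((x1 - matrix(q1, nrow(x1), 3, byrow = TRUE))^2) /
                     (2 * 0.75^2))) / (0.75 * sqrt(2 * pi))^3
  dens_all <- vapply(seq_along(m$by_class), function(j) {
    xj <- m$by_class[[j]]
    mean(exp(-rowSums((xj - matrix(q1, nrow(xj), 3, byrow = TRUE))^2) /
               (2 * 0.75^2))) / (0.75 * sqrt(2 * pi))^3
  }, numeric(1))
  expect_equal(unname(p[1, 1]), unname(m$prior[1] * dens / sum(m$prior * dens_all)),
               tolerance = 1e-9)
  expect_equal(unname(dens_all[1]), dens)
})

test_that("every family emits simplex probabilities on its contract", {
  set <- separable_training_set(n_rois_per_class = 2, n_vox = 30, seed = 32)
  q <- matrix(runif(60), 20, 3)
  cases <- list(LR = 1, SVM = 10, NN = 1e-4, NB = NULL, RF = 20, kNN = 10,
                KDE = 0.3, aKDE = NULL)
  for (fam in names(cases)) {
    m <- fit_classifier(fam, cases[[fam]], set, seed = 33)
    p <- predict_proba(m, q)
    expect_equal(dim(p), c(20, 4), info = fam)
    expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-9, info = fam)
    expect_true(all(p >= 0), info = fam)
  }
})

test_that("stochastic families honor the seed", {
  set <- separable_training_set(seed = 34)
  q <- matrix(runif(30), 10, 3)
  for (fam in c("RF", "NN")) {
    hp <- if (fam == "RF") 25 else 1e-3
    p1 <- predict_proba(fit_classifier(fam, hp, set, seed = 99), q)
    p2 <- predict_proba(fit_classifier(fam, hp, set, seed = 99), q)
    expect_identical(p1, p2, info = fam)
  }
})

test_that("classify_volume labels the VOI with lowest-id tie-breaking", {
  study <- generate_phantom(phantom_spec(shape = c(24, 24, 6), seed = 41,
                                         compartments = list(
    list(type = "block", class_id = 1L, center = c(7, 12, 3), radii = c(5, 10, 2)),
    list(type = "block", class_id = 3L, center = c(18, 12, 3), radii = c(4, 10, 2)))))
  field <- phantom_feature_field(study)
  tab <- phantom_training_rois(study, classes = c(1, 3), roi_side = 5,
                               n_per_class = 1, seed = 1)
  rois <- suppressWarnings(phantom_labeled_rois(study, tab))  # 25-voxel ROIs
  m <- fit_gaussian_nb(training_set(rois))
  res <- classify_volume(m, field, study$voi)
  ## well-separated classes: near-perfect agreement away from boundaries
  interior <- interior_mask(study$truth$labels)
  agree <- mean(res$labels$labels[interior] == study$truth$labels[interior])
  expect_gte(agree, 0.99)

  ## single-voxel VOI
  memb <- array(FALSE, dim(study$truth$labels)); memb[7, 12, 3] <- TRUE
  one <- classify_volume(m, field, mask_volume(memb, study$spec$spacing))
  expect_equal(sum(!is.na(one$labels$labels)), 1)

  expect_error(classify_volume(m, field,
                               mask_volume(array(FALSE, dim(memb)),
                                           study$spec$spacing)), "empty")

  ## exact probability ties resolve to the lowest class id
  tie <- m
  tie$mu[] <- 0.5; tie$sigma2[] <- 0.01; tie$prior <- c(0.5, 0.5)
  p <- predict_proba(tie, matrix(0.5, 1, 3))
  expect_equal(which.max(p), 1L)
  expect_equal(p[1], p[2])
})

test_that("NB model JSON round trip preserves the posterior", {
  m <- fit_gaussian_nb(random_training_df(seed = 42))
  path <- tempfile(fileext = ".json")
  write_nb_model(m, path)
  back <- read_nb_model(path)
  x <- matrix(runif(60), 20, 3)
  expect_equal(predict_proba(m, x), predict_proba(back, x), tolerance = 1e-12)
})
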