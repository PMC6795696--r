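## Independent oracles and small fixture builders shared across tests.

## Brute-force Bayes rule for a Gaussian NB model: explicit density
## products computed long-hand (no logs, no dnorm), independent of the
## package's prediction path.
nb_oracle <- function(model, x) {
  K <- length(model$classes)
  out <- matrix(0, nrow(x), K)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(K)) {
      p <- model$prior[j]
      for (d in 1:3) {
        s2 <- model$sigma2[j, d]
        p <- p * exp(-(x[i, d] - model$mu[j, d])^2 / (2 * s2)) /
          sqrt(2 * pi * s2)
      }
      out[i, j] <- p
    }
    out[i, ] <- out[i, ] / sum(out[i, ])
  }
  out
}

## Random well-spread training data over 5 classes in the unit cube.
random_training_df <- function(n_per_class = 40, seed = 1) {
  set.seed(seed)
  centers <- matrix(runif(15, 0.1, 0.9), 5, 3)
  do.call(rbind, lapply(1:5, function(k) {
    data.frame(roi_id = paste0("r", k), patient_id = "p1", class_id = k,
               adc_n = pmin(pmax(rnorm(n_per_class, centers[k, 1], 0.05), 0), 1),
               ef_n = pmin(pmax(rnorm(n_per_class, centers[k, 2], 0.05), 0), 1),
               ff_n = pmin(pmax(rnorm(n_per_class, centers[k, 3], 0.05), 0), 1))
  }))
}

## Tiny constant-spacing parameter volume.
toy_volume <- function(values, quantity, spacing = c(1, 1, 1)) {
  parameter_volume(values, spacing = spacing, quantity = quantity)
}

## A training set of well-separated classes: one tight Gaussian blob per
## class, several ROIs each. Separation / SD >= 6 by construction.
separable_training_set <- function(n_rois_per_class = 2, n_vox = 50,
                                   classes = 1:4, sd = 0.02, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0.2, 0.8, 0.1), c(0.25, 0.2, 0.1),
                   c(0.8, 0.2, 0.1), c(0.3, 0.5, 0.85),
                   c(0.6, 0.6, 0.5))
  rois <- list()
  for (k in classes) {
    for (r in seq_len(n_rois_per_class)) {
      samples <- cbind(
        pmin(pmax(rnorm(n_vox, centers[k, 1], sd), 0), 1),
        pmin(pmax(rnorm(n_vox, centers[k, 2], sd), 0), 1),
        pmin(pmax(rnorm(n_vox, centers[k, 3], sd), 0), 1))
      rois[[length(rois) + 1L]] <- labeled_roi(
        sprintf("c%dr%d", k, r), sprintf("pat%d", r), k, samples)
    }
  }
  training_set(rois)
}

## Random probability volume on a single slice (all voxels valid).
random_prob_slice <- function(nx = 16, ny = 16, K = 5, seed = 1) {
  set.seed(seed)
  p <- matrix(rexp(nx * ny * K), nx * ny, K)
  p <- p / rowSums(p)
  valid <- array(TRUE, c(nx, ny, 1))
  probability_volume(p, valid, seq_len(K), voxel_grid(c(nx, ny, 1)))
}

## Perturb a fraction of scored voxels: their probability row is replaced
## by one concentrated on a uniformly chosen wrong class, emulating
## boundary/classification noise.
perturb_probability_volume <- function(probs, fraction = 0.05, seed = 1) {
  set.seed(seed)
  sel <- which(probs$valid)
  n_flip <- round(fraction * length(sel))
  flip <- sample(sel, n_flip)
  K <- length(probs$classes)
  arr <- probs$probs
  shape <- dim(probs$valid)
  p_rows <- sapply(seq_len(K), function(j) arr[, , , j][probs$valid])
  if (!is.matrix(p_rows)) p_rows <- matrix(p_rows, nrow = 1)
  row_of <- match(flip, sel)
  for (i in seq_along(flip)) {
    cur <- which.max(p_rows[row_of[i], ])
    wrong <- sample(setdiff(seq_len(K), cur), 1)
    noisy <- rep(0.4 / (K - 1), K)
    noisy[wrong] <- 0.6
    p_rows[row_of[i], ] <- noisy
  }
  probability_volume(p_rows, probs$valid, probs$classes, probs$grid)
}

## Interior voxels of the ground-truth map: those whose in-slice
## 8-neighborhood shares their class (away from compartment boundaries).
interior_mask <- function(truth_labels) {
  shape <- dim(truth_labels)
  ok <- !is.na(truth_labels)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- array(NA_integer_, shape)
    xs <- seq_len(shape[1]) + dx; ys <- seq_len(shape[2]) + dy
    okx <- xs >= 1 & xs <= shape[1]; oky <- ys >= 1 & ys <= shape[2]
    shifted[okx, oky, ] <- truth_labels[xs[okx], ys[oky], ]
    ok <- ok & !is.na(shifted) & (shifted == truth_labels | is.na(truth_labels))
  }
  ok & !is.na(truth_labels)
}
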