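## Synthetic multi-parametric phantom studies with known habitat ground
## truth. The phantom emulates the tissue contrasts the five-class decision
## tree relies on (enhancing vs non-enhancing cellular tumor separated by
## EF, necrosis by high ADC, fat by high FF) with Gaussian class-conditional
## parameter noise clipped to the intrinsic ranges, and synthesizes raw
## Dixon / T1 signal pairs that are exact pre-images of the target FF / EF
## maps.

#' Default per-class parameter distributions
#'
#' Means and SDs for ADC (mm^2/s), EF (%) and FF (%) per tissue class,
#' chosen to respect the decision-tree contrasts: classes 1-2 low ADC and
#' separated by enhancement, class 3 high ADC, class 4 high fat fraction
#' with noise-dominated ADC. `background` is the non-tumor tissue outside
#' the VOI.
#'
#' @return data.frame, one row per class plus background.
#' @export
phantom_class_params <- function() {
  data.frame(
    class_id = c(1, 2, 3, 4, NA),
    name = c(habitat_classes()$name[1:4], "background"),
    adc_mean = c(0.9e-3, 1.0e-3, 2.4e-3, 1.0e-3, 1.4e-3),
    adc_sd = c(0.1e-3, 0.1e-3, 0.1e-3, 0.6e-3, 0.15e-3),
    ef_mean = c(60, 5, 5, 0, 10),
    ef_sd = c(8, 8, 8, 8, 6),
    ff_mean = c(5, 5, 5, 85, 20),
    ff_sd = c(4, 4, 4, 4, 5))
}

.default_compartments <- function() {
  list(
    list(type = "ellipsoid", class_id = 1L, center = c(32, 32, 8),
         radii = c(25, 25, 7)),
    list(type = "ellipsoid", class_id = 2L, center = c(24, 38, 8),
         radii = c(8, 8, 3)),
    list(type = "ellipsoid", class_id = 3L, center = c(42, 28, 8),
         radii = c(7, 7, 3)),
    list(type = "block", class_id = 4L, center = c(26, 22, 8),
         radii = c(6, 6, 2.5)))
}

#' Phantom study specification
#'
#' Compartments (ellipsoids or axis-aligned blocks) are painted in list
#' order, later entries overriding earlier ones, which is how nested
#' geometry (e.g. a necrotic core inside enhancing tumor) is expressed.
#' The VOI is the union of all compartments.
#'
#' @param shape grid shape, default 64 x 64 x 16.
#' @param spacing voxel spacing in mm, default 2 mm isotropic.
#' @param compartments list of compartments, each
#'   `list(type = "ellipsoid"|"block", class_id, center, radii)` in voxel
#'   coordinates (radii are half-widths for blocks).
#' @param class_params per-class distributions ([phantom_class_params()]).
#' @param blur boundary blur: SD in voxels of a Gaussian filter applied to
#'   the parameter maps (0 = sharp boundaries).
#' @param label_noise fraction of VOI voxels whose parameters are drawn
#'   from a random other tissue class (their ground-truth label is kept),
#'   emulating mislabeled or partial-volume voxels.
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 16L), spacing = c(2, 2, 2),
                         compartments = .default_compartments(),
                         class_params = phantom_class_params(),
                         blur = 0, label_noise = 0, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1), all(spacing > 0),
            blur >= 0, label_noise >= 0, label_noise < 1,
            length(compartments) >= 1)
  for (cp in compartments) {
    stopifnot(cp$type %in% c("ellipsoid", "block"), cp$class_id %in% 1:4,
              length(cp$center) == 3, length(cp$radii) == 3, all(cp$radii > 0))
  }
  p <- class_params
  stopifnot(all(p$adc_mean >= 0 & p$adc_mean <= 3e-3),
            all(p$ef_mean >= -100 & p$ef_mean <= 100),
            all(p$ff_mean >= 0 & p$ff_mean <= 100),
            all(p$adc_sd > 0), all(p$ef_sd > 0), all(p$ff_sd > 0))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 compartments = compartments, class_params = class_params,
                 blur = blur, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.paint_compartments <- function(spec) {
  shape <- spec$shape
  ix <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape)
  iy <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              shape)
  iz <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  labels <- array(NA_integer_, shape)
  for (cp in spec$compartments) {
    inside <- if (cp$type == "ellipsoid") {
      ((ix - cp$center[1]) / cp$radii[1])^2 +
        ((iy - cp$center[2]) / cp$radii[2])^2 +
        ((iz - cp$center[3]) / cp$radii[3])^2 <= 1
    } else {
      abs(ix - cp$center[1]) <= cp$radii[1] &
        abs(iy - cp$center[2]) <= cp$radii[2] &
        abs(iz - cp$center[3]) <= cp$radii[3]
    }
    labels[inside] <- cp$class_id
  }
  labels
}

.gauss_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    padded <- rbind(m[rep(1, r), , drop = FALSE], m,
                    m[rep(d[1], r), , drop = FALSE])
    out <- matrix(0, d[1], ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * padded[(j - 1) + seq_len(d[1]), ]
    arr <- aperm(array(out, d), order(perm))
  }
  arr
}

#' Generate a phantom study
#'
#' Paints the compartment geometry, draws per-voxel ADC/EF/FF from each
#' voxel's class distribution (Gaussian, clipped to the intrinsic ranges
#' ADC in \[0, 3\]e-3 mm^2/s, EF in \[-100, 100\] %, FF in \[0, 100\] %),
#' optionally blurs boundaries, and synthesizes raw Dixon and pre/post-T1
#' signal pairs whose fat-fraction and enhancement-fraction maps reproduce
#' the target FF / EF exactly.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_study`: list with [parameter_volume()]s `adc`, `ef`,
#'   `ff`, `s_fat`, `s_water`, `s_pre`, `s_post`, the `voi` [mask_volume()],
#'   the ground-truth `truth` (a `habitat_map`) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  restore <- .with_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  truth <- .paint_compartments(spec)
  voi <- !is.na(truth)
  shape <- spec$shape
  n <- prod(shape)
  params <- spec$class_params
  ## row of class_params generating each voxel (background = last row)
  gen_class <- truth
  draw_row <- ifelse(is.na(gen_class), nrow(params), match(gen_class, params$class_id))
  if (spec$label_noise > 0) {
    in_voi <- which(voi)
    n_noise <- round(spec$label_noise * length(in_voi))
    if (n_noise > 0) {
      flip <- sample(in_voi, n_noise)
      draw_row[flip] <- vapply(draw_row[flip], function(r) {
        sample(setdiff(1:4, r), 1L)
      }, integer(1))
    }
  }
  adc <- pmin(pmax(rnorm(n, params$adc_mean[draw_row],
                         params$adc_sd[draw_row]), 0), 3e-3)
  ef <- pmin(pmax(rnorm(n, params$ef_mean[draw_row],
                        params$ef_sd[draw_row]), -100), 100)
  ff <- pmin(pmax(rnorm(n, params$ff_mean[draw_row],
                        params$ff_sd[draw_row]), 0), 100)
  adc <- .gauss_blur3d(array(adc, shape), spec$blur)
  ef <- .gauss_blur3d(array(ef, shape), spec$blur)
  ff <- .gauss_blur3d(array(ff, shape), spec$blur)
  ## exact signal-pair pre-images: FF = fat/(fat+water)*100 with total 200,
  ## EF = (post-pre)/(post+pre)*100 with total 200
  s_fat <- ff / 100 * 200
  s_water <- 200 - s_fat
  s_post <- 100 * (1 + ef / 100)
  s_pre <- 100 * (1 - ef / 100)
  sp <- spec$spacing
  pv <- function(vals, quantity, label)
    parameter_volume(array(vals, shape), sp, quantity, label = label)
  structure(list(
    adc = pv(adc, "ADC mm^2/s", "phantom ADC"),
    ef = pv(ef, "EF %", "phantom EF"),
    ff = pv(ff, "FF %", "phantom FF"),
    s_fat = pv(s_fat, "signal a.u.", "phantom Dixon fat"),
    s_water = pv(s_water, "signal a.u.", "phantom Dixon water"),
    s_pre = pv(s_pre, "signal a.u.", "phantom T1 pre"),
    s_post = pv(s_post, "signal a.u.", "phantom T1 post"),
    voi = mask_volume(voi, sp, label = "phantom VOI"),
    truth = habitat_map(truth, voxel_grid(shape, sp)),
    spec = spec),
    class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("phantom_study %s, VOI %d voxels, seed %d\n",
              format(x$truth$grid), sum(x$voi$membership), x$spec$seed))
  invisible(x)
}

#' Place square training ROIs inside phantom compartments
#'
#' Finds, for each requested class, axial square ROIs lying entirely in the
#' interior of that class's region (every voxel of the square and its
#' margin shares the class), mimicking expert ROIs drawn far from visible
#' boundaries. Placement is seeded and non-overlapping.
#'
#' @param study a `phantom_study`.
#' @param classes classes to place ROIs for; defaults to every tissue class
#'   present in the ground truth.
#' @param roi_side side of the square in voxels (default 7, i.e. 49
#'   voxels, within the 45-100 voxel expert-ROI range).
#' @param n_per_class ROIs per class.
#' @param margin boundary clearance in voxels.
#' @param seed integer seed for placement.
#' @return data.frame (`roi_id`, `class_id`, `x`, `y`, `z`, `side`) with
#'   the ROI masks in the `masks` attribute (named list of
#'   [mask_volume()]s).
#' @export
phantom_training_rois <- function(study, classes = NULL, roi_side = 7L,
                                  n_per_class = 2L, margin = 1L, seed = 1L) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  truth <- study$truth$labels
  if (is.null(classes)) classes <- sort(unique(truth[!is.na(truth)]))
  shape <- dim(truth)
  h <- (roi_side - 1L) %/% 2L + margin
  rows <- list(); masks <- list()
  for (k in classes) {
    inside <- !is.na(truth) & truth == k
    ## erode: keep voxels whose whole (side+2*margin)^2 in-slice square is class k
    ok <- inside
    for (dx in -h:h) for (dy in -h:h) {
      if (dx == 0 && dy == 0) next
      shifted <- array(FALSE, shape)
      xs <- seq_len(shape[1]) + dx; ys <- seq_len(shape[2]) + dy
      okx <- xs >= 1 & xs <= shape[1]; oky <- ys >= 1 & ys <= shape[2]
      shifted[okx, oky, ] <- inside[xs[okx], ys[oky], ]
      ok <- ok & shifted
    }
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) == 0) stop("no interior placement for class ", k,
                              " with roi_side ", roi_side)
    placed <- 0L
    order_idx <- sample(nrow(cand))
    centers <- matrix(numeric(0), ncol = 3)
    for (i in order_idx) {
      ctr <- cand[i, ]
      if (nrow(centers) &&
          any(abs(centers[, 1] - ctr[1]) < roi_side &
              abs(centers[, 2] - ctr[2]) < roi_side &
              centers[, 3] == ctr[3])) next
      placed <- placed + 1L
      centers <- rbind(centers, ctr)
      half <- (roi_side - 1L) %/% 2L
      memb <- array(FALSE, shape)
      memb[(ctr[1] - half):(ctr[1] + half),
           (ctr[2] - half):(ctr[2] + half), ctr[3]] <- TRUE
      roi_id <- sprintf("class%d_roi%02d", k, placed)
      masks[[roi_id]] <- mask_volume(memb, study$spec$spacing, label = roi_id)
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = roi_id, class_id = k, x = ctr[1], y = ctr[2], z = ctr[3],
        side = roi_side)
      if (placed >= n_per_class) break
    }
    if (placed < n_per_class) {
      stop("could only place ", placed, " ROI(s) for class ", k)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "masks") <- masks
  out
}

#' Extract labeled ROIs from a phantom study
#'
#' Convenience wrapper: computes FF/EF from the phantom's raw signal pairs,
#' normalizes the feature field and extracts one [labeled_roi()] per ROI
#' placed by [phantom_training_rois()].
#'
#' @param study a `phantom_study`.
#' @param roi_table output of [phantom_training_rois()].
#' @param patient_id patient id recorded on the ROIs.
#' @return List of [labeled_roi()]s.
#' @export
phantom_labeled_rois <- function(study, roi_table, patient_id = "phantom") {
  field <- phantom_feature_field(study)
  masks <- attr(roi_table, "masks")
  lapply(seq_len(nrow(roi_table)), function(i) {
    extract_roi_samples(field, masks[[roi_table$roi_id[i]]],
                        roi_table$class_id[i], roi_id = roi_table$roi_id[i],
                        patient_id = patient_id)
  })
}

#' Normalized feature field of a phantom study, via the map pipeline
#'
#' Recomputes FF and EF from the synthesized raw signal pairs (exercising
#' the same code path as real data) and normalizes.
#'
#' @param study a `phantom_study`.
#' @return A `feature_field`.
#' @export
phantom_feature_field <- function(study) {
  ff <- compute_fat_fraction(study$s_fat, study$s_water)
  ef <- compute_enhancement_fraction(study$s_pre, study$s_post)
  normalize_features(study$adc, ef, ff)
}

#' Generate a pre/post-treatment phantom pair
#'
#' The post-treatment study shares the pre-treatment geometry but applies a
#' designed response model: class-to-class conversion of a fraction of
#' voxels (e.g. enhancing tumor devascularizing into the non-enhancing
#' class) and per-class ADC mean shifts (e.g. treatment-induced diffusion
#' increase). The exact designed deltas are recorded for recovery testing.
#'
#' @param spec_pre [phantom_spec()] for the baseline study.
#' @param conversions list of `list(from, to, fraction)` class conversions.
#' @param adc_shift named numeric: ADC mean shift (mm^2/s) per class id.
#' @param seed integer seed (pre study uses `spec_pre$seed`, post draws use
#'   `seed`).
#' @return List with `pre`, `post` (both `phantom_study`) and `designed`
#'   (per-class designed `delta_fraction` and `delta_mean_adc`).
#' @export
generate_longitudinal_pair <- function(spec_pre,
                                       conversions = list(),
                                       adc_shift = numeric(0),
                                       seed = spec_pre$seed + 1L) {
  pre <- generate_phantom(spec_pre)
  params_post <- spec_pre$class_params
  for (k in names(adc_shift)) {
    r <- match(as.integer(k), params_post$class_id)
    params_post$adc_mean[r] <- params_post$adc_mean[r] + adc_shift[[k]]
  }
  if (any(params_post$adc_mean < 0 | params_post$adc_mean > 3e-3)) {
    stop("ADC shift pushes a class mean outside [0, 3e-3] mm^2/s")
  }
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  truth_post <- pre$truth$labels
  for (cv in conversions) {
    stopifnot(cv$from %in% 1:4, cv$to %in% 1:4, cv$fraction >= 0,
              cv$fraction <= 1)
    idx <- which(truth_post == cv$from)
    n_flip <- round(cv$fraction * length(idx))
    if (n_flip > 0) truth_post[sample(idx, n_flip)] <- cv$to
  }
  spec_post <- spec_pre
  spec_post$class_params <- params_post
  spec_post$seed <- as.integer(spec_pre$seed + 7919L)
  post <- .phantom_from_labels(spec_post, truth_post, !is.na(truth_post))
  cnt <- function(lab) vapply(1:5, function(k) sum(lab == k, na.rm = TRUE),
                              numeric(1))
  n_pre <- cnt(pre$truth$labels); n_post <- cnt(truth_post)
  designed <- data.frame(
    class_id = 1:5,
    delta_fraction = n_post / sum(n_post) - n_pre / sum(n_pre),
    delta_mean_adc = vapply(1:5, function(k) {
      if (as.character(k) %in% names(adc_shift)) adc_shift[[as.character(k)]]
      else 0
    }, numeric(1)))
  list(pre = pre, post = post, designed = designed)
}

## Build a phantom study from an explicit ground-truth label array.
.phantom_from_labels <- function(spec, truth, voi) {
  restore <- .with_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  shape <- spec$shape
  n <- prod(shape)
  params <- spec$class_params
  draw_row <- ifelse(is.na(truth), nrow(params), match(truth, params$class_id))
  adc <- pmin(pmax(rnorm(n, params$adc_mean[draw_row],
                         params$adc_sd[draw_row]), 0), 3e-3)
  ef <- pmin(pmax(rnorm(n, params$ef_mean[draw_row],
                        params$ef_sd[draw_row]), -100), 100)
  ff <- pmin(pmax(rnorm(n, params$ff_mean[draw_row],
                        params$ff_sd[draw_row]), 0), 100)
  s_fat <- ff / 100 * 200
  s_water <- 200 - s_fat
  s_post <- 100 * (1 + ef / 100)
  s_pre <- 100 * (1 - ef / 100)
  sp <- spec$spacing
  pv <- function(vals, quantity, label)
    parameter_volume(array(vals, shape), sp, quantity, label = label)
  structure(list(
    adc = pv(adc, "ADC mm^2/s", "phantom ADC"),
    ef = pv(ef, "EF %", "phantom EF"),
    ff = pv(ff, "FF %", "phantom FF"),
    s_fat = pv(s_fat, "signal a.u.", "phantom Dixon fat"),
    s_water = pv(s_water, "signal a.u.", "phantom Dixon water"),
    s_pre = pv(s_pre, "signal a.u.", "phantom T1 pre"),
    s_post = pv(s_post, "signal a.u.", "phantom T1 post"),
    voi = mask_volume(voi, sp, label = "phantom VOI"),
    truth = habitat_map(truth, voxel_grid(shape, sp)),
    spec = spec),
    class = "phantom_study")
}
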