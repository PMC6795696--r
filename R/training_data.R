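## Labeled training data: class taxonomy, ROI sample extraction, synthesis
## of the uniform "novelty" class, and assembly into cross-validation /
## held-out test sets.

#' The five-class habitat taxonomy
#'
#' Classes 1-4 are tissue types placed by an expert (enhancing cellular
#' tumor, non-enhancing cellular tumor, necrotic/cystic, fat); class 5 is
#' the synthetic "novelty" catch-all trained on uniform samples of the
#' whole feature space so that voxels unlike any training tissue are
#' flagged rather than forced into a tissue class.
#'
#' @return data.frame with columns `id`, `name`, `color`.
#' @export
habitat_classes <- function() {
  data.frame(
    id = 1:5,
    name = c("enhancing cellular tumor", "non-enhancing cellular tumor",
             "necrotic/cystic", "fat", "novelty"),
    color = c("red", "green", "blue", "yellow", "gray"),
    stringsAsFactors = FALSE)
}

#' Construct a labeled ROI
#'
#' @param roi_id unique ROI identifier.
#' @param patient_id patient the ROI was drawn in (`"synthetic"` for
#'   novelty ROIs).
#' @param class_id habitat class 1-5.
#' @param samples numeric matrix of normalized feature rows
#'   (`adc_n`, `ef_n`, `ff_n`), all in \[0, 1\].
#' @param timepoint `"pre"` or `"post"`.
#' @return An object of class `labeled_roi`.
#' @export
labeled_roi <- function(roi_id, patient_id, class_id, samples, timepoint = "pre") {
  class_id <- as.integer(class_id)
  stopifnot(class_id %in% 1:5, is.matrix(samples), ncol(samples) == 3,
            nrow(samples) >= 1)
  if (any(!is.finite(samples)) || any(samples < 0) || any(samples > 1)) {
    stop("ROI samples must be finite and inside [0,1]^3")
  }
  colnames(samples) <- c("adc_n", "ef_n", "ff_n")
  structure(list(roi_id = as.character(roi_id),
                 patient_id = as.character(patient_id),
                 class_id = class_id,
                 samples = samples,
                 voxel_count = nrow(samples),
                 timepoint = timepoint),
            class = "labeled_roi")
}

#' Extract labeled samples for one training ROI
#'
#' Pulls one normalized feature row per voxel of the ROI mask that is valid
#' in all three parameter maps. Expert ROIs are squares of area 1-2 cm^2
#' (45-100 voxels); a count outside that range triggers a warning, not an
#' error, since phantom ROIs may be sized differently.
#'
#' @param features a `feature_field` from [normalize_features()].
#' @param roi_mask [mask_volume()] for the ROI.
#' @param class_id tissue class 1-4 (class 5 is never image-derived; see
#'   [synthesize_novelty_rois()]).
#' @param roi_id,patient_id,timepoint ROI metadata.
#' @return A [labeled_roi()].
#' @export
extract_roi_samples <- function(features, roi_mask, class_id,
                                roi_id = roi_mask$label, patient_id = "unknown",
                                timepoint = "pre") {
  stopifnot(class_id %in% 1:4)
  if (!any(roi_mask$membership)) stop("ROI mask is empty")
  samples <- feature_matrix(features, roi_mask)
  if (nrow(samples) == 0) stop("ROI has no voxels valid in all three maps")
  if (nrow(samples) < 45 || nrow(samples) > 100) {
    warning(sprintf("ROI '%s' has %d voxels, outside the expected 45-100 range",
                    roi_id, nrow(samples)))
  }
  labeled_roi(roi_id, patient_id, class_id, samples, timepoint)
}

#' Synthesize the uniform novelty class
#'
#' Draws ROIs of class 5 by sampling uniformly over the intrinsic parameter
#' ranges -- EF in \[-100, 100\] %, FF in \[0, 100\] %, ADC in \[0, 3\]e-3
#' mm^2/s -- then passing the draws through the standard normalization, so
#' every normalized component is Uniform(0, 1). The number of voxels per
#' ROI is drawn uniformly from the expert-ROI size range.
#'
#' @param n_rois number of synthetic ROIs (default 15).
#' @param voxels_per_roi integer range to draw each ROI's voxel count from.
#' @param seed integer seed; the draw is fully reproducible.
#' @return List of [labeled_roi()]s, all class 5, patient `"synthetic"`.
#' @export
synthesize_novelty_rois <- function(n_rois = 15, voxels_per_roi = c(45L, 100L),
                                    seed = 1L) {
  stopifnot(n_rois >= 1)
  rng <- .with_seed(seed)
  on.exit(rng(), add = TRUE)
  lapply(seq_len(n_rois), function(i) {
    n <- sample(seq.int(voxels_per_roi[1], voxels_per_roi[2]), 1L)
    samples <- normalize_feature_rows(adc = runif(n, 0, 3e-3),
                                      ef = runif(n, -100, 100),
                                      ff = runif(n, 0, 100))
    labeled_roi(sprintf("novelty_%02d", i), "synthetic", 5L, samples)
  })
}

## Save/restore the RNG state so seeded helpers do not disturb the caller's
## random stream.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Bundle labeled ROIs into a training set
#'
#' @param rois list of [labeled_roi()]s.
#' @param require_all_classes error unless every class 1-5 has at least one
#'   ROI (needed to fit a 5-class model).
#' @return An object of class `training_set` with elements `rois`,
#'   `class_counts` (ROIs per class) and `data` (pooled per-voxel
#'   data.frame: `roi_id`, `patient_id`, `class_id`, `adc_n`, `ef_n`, `ff_n`).
#' @export
training_set <- function(rois, require_all_classes = FALSE) {
  stopifnot(length(rois) >= 1)
  ids <- vapply(rois, function(r) r$roi_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate roi_id in training set")
  cls <- vapply(rois, function(r) r$class_id, integer(1))
  counts <- vapply(1:5, function(k) sum(cls == k), integer(1))
  names(counts) <- as.character(1:5)
  if (require_all_classes && any(counts == 0)) {
    stop("classes with no ROI: ", paste(which(counts == 0), collapse = ", "))
  }
  data <- do.call(rbind, lapply(rois, function(r) {
    data.frame(roi_id = r$roi_id, patient_id = r$patient_id,
               class_id = r$class_id,
               adc_n = r$samples[, 1], ef_n = r$samples[, 2],
               ff_n = r$samples[, 3], stringsAsFactors = FALSE)
  }))
  rownames(data) <- NULL
  structure(list(rois = rois, class_counts = counts, data = data),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d ROIs, %d voxels\n  ROIs per class: %s\n",
              length(x$rois), nrow(x$data),
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = " ")))
  invisible(x)
}

#' @export
as.data.frame.training_set <- function(x, ...) x$data

#' Split ROIs into cross-validation and held-out test sets
#'
#' Mirrors the leave-one-patient-out protocol: all image ROIs of the
#' held-out patients form the test set; everything else (plus all synthetic
#' novelty ROIs) forms the cross-validation set. Fitting a 5-class model
#' requires every class to survive the split.
#'
#' @param image_rois list of image-derived [labeled_roi()]s (classes 1-4).
#' @param novelty_rois list of class-5 ROIs from [synthesize_novelty_rois()].
#' @param holdout_patients character vector of patient ids to hold out
#'   (possibly empty).
#' @return List with `cv_set` and `test_set` (`test_set` is `NULL` when no
#'   patient is held out).
#' @export
assemble_training_set <- function(image_rois, novelty_rois = list(),
                                  holdout_patients = character(0)) {
  pats <- vapply(image_rois, function(r) r$patient_id, character(1))
  unknown <- setdiff(holdout_patients, pats)
  if (length(unknown)) stop("holdout patient(s) not present: ",
                            paste(unknown, collapse = ", "))
  held <- pats %in% holdout_patients
  cv_rois <- c(image_rois[!held], novelty_rois)
  cv_set <- training_set(cv_rois)
  cls_cv <- vapply(cv_rois, function(r) r$class_id, integer(1))
  cls_all <- c(vapply(image_rois, function(r) r$class_id, integer(1)),
               vapply(novelty_rois, function(r) r$class_id, integer(1)))
  lost <- setdiff(unique(cls_all), unique(cls_cv))
  if (length(lost)) {
    stop("holdout removes every ROI of class(es): ", paste(lost, collapse = ", "))
  }
  test_set <- if (any(held)) training_set(image_rois[held]) else NULL
  list(cv_set = cv_set, test_set = test_set)
}

#' Write / read a training set as a per-voxel CSV
#'
#' One row per voxel: `roi_id`, `patient_id`, `class_id`, `adc_n`, `ef_n`,
#' `ff_n`.
#'
#' @param set a `training_set`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `training_set` (read).
#' @export
write_training_set <- function(set, path) {
  write.csv(set$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "patient_id", "class_id", "adc_n", "ef_n", "ff_n")
  if (!all(need %in% names(df))) {
    stop("training-set CSV must have columns: ", paste(need, collapse = ", "))
  }
  rois <- lapply(split(df, df$roi_id), function(d) {
    labeled_roi(d$roi_id[1], d$patient_id[1], d$class_id[1],
                as.matrix(d[, c("adc_n", "ef_n", "ff_n")]))
  })
  training_set(unname(rois))
}
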