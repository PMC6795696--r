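## Exhaustive one-ROI-per-class cross-validation: every Cartesian
## combination of one held-out ROI per class is a training/validation
## cycle; the hyperparameter maximizing the median accuracy over cycles is
## selected.

#' Enumerate validation ROI combinations
#'
#' Builds the Cartesian product of the per-class ROI id lists: each tuple
#' holds exactly one ROI of every class present, and the number of tuples
#' is the product of the per-class ROI counts. Tuples are emitted in
#' deterministic lexicographic order (class 1 id varying slowest).
#'
#' @param cv_set a `training_set`.
#' @return data.frame with one column per class (named `class_<id>`), one
#'   row per validation combination; ROI ids as character.
#' @export
enumerate_validation_combinations <- function(cv_set) {
  cls <- vapply(cv_set$rois, function(r) r$class_id, integer(1))
  ids <- vapply(cv_set$rois, function(r) r$roi_id, character(1))
  classes <- sort(unique(cls))
  if (!length(classes)) stop("training set has no ROIs")
  per_class <- lapply(classes, function(k) sort(ids[cls == k]))
  if (any(vapply(per_class, length, integer(1)) == 0L)) stop("empty class")
  ## expand.grid varies the first factor fastest; reverse so class 1 is slowest
  grid <- expand.grid(rev(per_class), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(per_class)), drop = FALSE]
  names(grid) <- paste0("class_", classes)
  rownames(grid) <- NULL
  grid
}

#' Run exhaustive cross-validation for one model family
#'
#' For every hyperparameter value and every validation combination, the
#' model is trained on all ROIs outside the combination and scored on the
#' pooled voxels of the held-out ROIs; accuracy is the percentage of voxels
#' whose predicted class equals their ROI label. A class contributing a
#' single ROI keeps that ROI in the training set even while it is being
#' validated (the only way to keep the class in a 5-class model); cycles
#' affected are flagged in the `leaky` column.
#'
#' @param cv_set a `training_set` with >= 1 ROI per class.
#' @param family model family (see [fit_classifier()]).
#' @param hp_grid numeric vector of hyperparameter values (use `NA` for the
#'   hyperparameter-free NB / aKDE families).
#' @param seed integer seed forwarded to stochastic fits.
#' @return List with `results` (one row per (hyperparameter, cycle):
#'   accuracy plus per-class accuracies) and `curve` (a
#'   `hyperparameter_curve`: per-value median/IQR/5-95th percentiles and
#'   the selected optimum).
#' @export
run_cv <- function(cv_set, family, hp_grid = NA, seed = 1L) {
  combos <- enumerate_validation_combinations(cv_set)
  cls <- vapply(cv_set$rois, function(r) r$class_id, integer(1))
  ids <- vapply(cv_set$rois, function(r) r$roi_id, character(1))
  singleton_classes <- as.integer(names(which(table(cls) == 1L)))
  rows <- list()
  for (hp in hp_grid) {
    hp_val <- if (is.na(hp)) NULL else hp
    for (i in seq_len(nrow(combos))) {
      val_ids <- as.character(combos[i, ])
      keep <- !(ids %in% val_ids) | (cls %in% singleton_classes)
      train <- training_set(cv_set$rois[keep])
      model <- fit_classifier(family, hp_val, train, seed = seed)
      val <- training_set(cv_set$rois[ids %in% val_ids])
      acc <- .cycle_accuracy(model, val)
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, hyperparameter = hp, cycle = i,
        validation_rois = paste(val_ids, collapse = "|"),
        leaky = any(cls[ids %in% val_ids] %in% singleton_classes),
        accuracy = acc$overall, t(acc$per_class),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  curve <- hyperparameter_curve(results)
  list(results = results, curve = curve)
}

.cycle_accuracy <- function(model, val_set) {
  x <- as.matrix(val_set$data[, c("adc_n", "ef_n", "ff_n")])
  truth <- val_set$data$class_id
  p <- predict_proba(model, x)
  pred <- model$classes[max.col(p, ties.method = "first")]
  per_class <- vapply(1:5, function(k) {
    n <- sum(truth == k)
    if (n == 0) NA_real_ else 100 * sum(pred[truth == k] == k) / n
  }, numeric(1))
  names(per_class) <- paste0("acc_class_", 1:5)
  list(overall = 100 * mean(pred == truth), per_class = per_class)
}

#' Summarize accuracies over the hyperparameter grid
#'
#' @param results the per-cycle results of [run_cv()].
#' @return A `hyperparameter_curve` data.frame: per hyperparameter value
#'   the median, quartiles and 5th/95th percentiles of the cycle
#'   accuracies, with the selected optimum in the `optimum` attribute.
#' @export
hyperparameter_curve <- function(results) {
  if (all(is.na(results$hyperparameter))) {
    ## hyperparameter-free family: a single accuracy distribution
    a <- results$accuracy
    curve <- data.frame(hyperparameter = NA_real_, median = median(a),
                        q25 = unname(quantile(a, 0.25)),
                        q75 = unname(quantile(a, 0.75)),
                        q05 = unname(quantile(a, 0.05)),
                        q95 = unname(quantile(a, 0.95)))
    class(curve) <- c("hyperparameter_curve", "data.frame")
    attr(curve, "family") <- results$family[1]
    attr(curve, "optimum") <- NA_real_
    return(curve)
  }
  sp <- split(results$accuracy, results$hyperparameter)
  hp <- as.numeric(names(sp))
  o <- order(hp)
  curve <- data.frame(
    hyperparameter = hp[o],
    median = vapply(sp, median, numeric(1))[o],
    q25 = vapply(sp, function(a) unname(quantile(a, 0.25)), numeric(1))[o],
    q75 = vapply(sp, function(a) unname(quantile(a, 0.75)), numeric(1))[o],
    q05 = vapply(sp, function(a) unname(quantile(a, 0.05)), numeric(1))[o],
    q95 = vapply(sp, function(a) unname(quantile(a, 0.95)), numeric(1))[o],
    row.names = NULL)
  class(curve) <- c("hyperparameter_curve", "data.frame")
  attr(curve, "family") <- results$family[1]
  attr(curve, "optimum") <- select_hyperparameter(curve)
  curve
}

#' Select the optimal hyperparameter
#'
#' The value with the highest median cross-validation accuracy; ties are
#' broken toward the smallest value on the grid, favoring the smoother /
#' simpler model.
#'
#' @param curve a `hyperparameter_curve`.
#' @return The selected hyperparameter value (scalar).
#' @export
select_hyperparameter <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  best <- which(curve$median == max(curve$median))
  curve$hyperparameter[min(best)]
}

#' Compare two families' accuracy distributions
#'
#' Two-sided Welch t-test on the per-cycle accuracies, flagged at the
#' p < 0.05 significance level with the stricter p < 0.005 and p < 0.0005
#' annotation thresholds also reported. If both arms have zero variance
#' the comparison is degenerate and no p-value is produced.
#'
#' @param results_a,results_b numeric vectors of cycle accuracies (>= 2 each).
#' @return List with `t`, `p`, `significant` and annotation flags; or a
#'   degenerate report with `degenerate = TRUE`.
#' @export
compare_families <- function(results_a, results_b) {
  stopifnot(length(results_a) >= 2, length(results_b) >= 2)
  if (var(results_a) == 0 && var(results_b) == 0) {
    return(list(degenerate = TRUE, t = NA_real_, p = NA_real_,
                significant = NA,
                mean_a = mean(results_a), mean_b = mean(results_b)))
  }
  tt <- t.test(results_a, results_b, alternative = "two.sided",
               var.equal = FALSE)
  list(degenerate = FALSE,
       t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05,
       p_lt_0.005 = tt$p.value < 0.005,
       p_lt_0.0005 = tt$p.value < 0.0005,
       mean_a = mean(results_a), mean_b = mean(results_b))
}

#' Score fitted models on a held-out test set
#'
#' Pooled-voxel accuracy per family on the ROIs of a held-out patient.
#' Classes absent from the training data are still scored (and count as
#' errors unless captured by the novelty class).
#'
#' @param models named list of fitted `habitat_classifier`s.
#' @param test_set a `training_set` of held-out ROIs.
#' @return Named numeric vector of accuracies (percent).
#' @export
evaluate_on_test <- function(models, test_set) {
  if (is.null(test_set) || nrow(test_set$data) == 0) stop("test set is empty")
  vapply(models, function(m) .cycle_accuracy(m, test_set)$overall, numeric(1))
}

#' Log-spaced hyperparameter grid for a family
#'
#' 25 log-spaced points across the family's search range (integer-valued
#' families are rounded and deduplicated); `NA` for NB / aKDE.
#'
#' @param family model family tag.
#' @param n number of grid points.
#' @return Numeric vector.
#' @export
default_hp_grid <- function(family, n = 25) {
  family <- match.arg(family, .FAMILIES)
  rng <- .HP_RANGES[[family]]
  if (is.null(rng)) return(NA)
  g <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
  if (family %in% c("RF", "kNN")) g <- unique(round(g))
  g
}
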