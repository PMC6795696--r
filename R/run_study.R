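## End-to-end orchestration: parameter maps -> training assembly ->
## (optional cross-validation) -> classifier fit -> whole-VOI prediction ->
## MRF smoothing -> habitat summary, with a JSON provenance report. All
## randomness flows from the single top-level seed.

#' Build and validate a study configuration
#'
#' Two input modes are supported: `files` (NIfTI volumes plus an ROI table
#' CSV with columns `roi_id`, `patient_id`, `timepoint`, `class_id`,
#' `mask_path`) and `phantom` (a seeded synthetic study with known ground
#' truth, in which case training ROIs are placed automatically).
#'
#' @param mode `"files"` or `"phantom"`.
#' @param paths named list of input paths (mode `"files"`): `dixon_fat`,
#'   `dixon_water`, `t1_pre`, `t1_post`, `adc`, `voi`, `roi_table`.
#' @param phantom a [phantom_spec()] (mode `"phantom"`).
#' @param family classifier family, default `"NB"`.
#' @param hyperparameter family hyperparameter; `"auto"` selects it by
#'   exhaustive cross-validation over the default grid.
#' @param n_novelty_rois synthetic novelty ROIs to add (default 15).
#' @param mrf an [mrf_config()].
#' @param out_dir output directory, or `NULL` to skip file outputs.
#' @param seed master seed for every stochastic stage.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("phantom", "files"), paths = list(),
                         phantom = phantom_spec(), family = "NB",
                         hyperparameter = NULL, n_novelty_rois = 15L,
                         mrf = mrf_config(), out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files") {
    need <- c("dixon_fat", "dixon_water", "t1_pre", "t1_post", "adc", "voi",
              "roi_table")
    missing <- setdiff(need, names(paths))
    if (length(missing)) stop("missing path(s): ", paste(missing, collapse = ", "))
    for (p in unlist(paths[need])) {
      if (!file.exists(p)) stop("input does not exist: ", p)
    }
  }
  family <- match.arg(family, .FAMILIES)
  structure(list(mode = mode, paths = paths, phantom = phantom,
                 family = family, hyperparameter = hyperparameter,
                 n_novelty_rois = as.integer(n_novelty_rois), mrf = mrf,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

## Deterministic sub-seeds so stages are reproducible yet use distinct
## streams; kept below 2^31.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12289L) %% 2147483646L) + 1L
}

#' Run a full habitat-mapping study
#'
#' Executes the pipeline compute-maps -> training assembly (image ROIs +
#' synthesized novelty class) -> optional hyperparameter cross-validation
#' -> classifier fit -> whole-VOI classification -> MRF de-noising ->
#' habitat summary. Any stage failure aborts with the stage name. When
#' `out_dir` is set, the label map, habitat summary and a JSON report with
#' seed and per-stage provenance are written there.
#'
#' @param config a [study_config()].
#' @return A `study_report` list: `config` echo, `summary`
#'   (a `habitat_summary`), `labels_raw` and `labels` (habitat maps before
#'   and after MRF), `probs`, `mrf` (traces and median iterations),
#'   `cv` (when hyperparameter = "auto"), `recovery` (phantom mode:
#'   agreement with ground truth), `stages` (status per stage).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stages <- character(0)
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages[[name]] <<- "ok"
    res
  }

  inputs <- step("load-inputs", {
    if (config$mode == "phantom") {
      study <- generate_phantom(config$phantom)
      list(study = study, voi = study$voi, adc = study$adc,
           s_fat = study$s_fat, s_water = study$s_water,
           s_pre = study$s_pre, s_post = study$s_post)
    } else {
      list(study = NULL,
           voi = read_mask(config$paths$voi, "VOI"),
           adc = read_volume(config$paths$adc, "ADC mm^2/s"),
           s_fat = read_volume(config$paths$dixon_fat, "signal a.u."),
           s_water = read_volume(config$paths$dixon_water, "signal a.u."),
           s_pre = read_volume(config$paths$t1_pre, "signal a.u."),
           s_post = read_volume(config$paths$t1_post, "signal a.u."))
    }
  })

  features <- step("compute-maps", {
    ff <- compute_fat_fraction(inputs$s_fat, inputs$s_water)
    ef <- compute_enhancement_fraction(inputs$s_pre, inputs$s_post)
    normalize_features(inputs$adc, ef, ff)
  })

  training <- step("make-training", {
    image_rois <- if (config$mode == "phantom") {
      tab <- phantom_training_rois(inputs$study,
                                   seed = .derive_seed(config$seed, 1L))
      phantom_labeled_rois(inputs$study, tab)
    } else {
      tab <- read.csv(config$paths$roi_table, stringsAsFactors = FALSE)
      base <- dirname(config$paths$roi_table)
      lapply(seq_len(nrow(tab)), function(i) {
        mp <- tab$mask_path[i]
        if (!file.exists(mp)) mp <- file.path(base, mp)
        extract_roi_samples(features, read_mask(mp, tab$roi_id[i]),
                            tab$class_id[i], roi_id = tab$roi_id[i],
                            patient_id = tab$patient_id[i],
                            timepoint = tab$timepoint[i])
      })
    }
    novelty <- synthesize_novelty_rois(config$n_novelty_rois,
                                       seed = .derive_seed(config$seed, 2L))
    assemble_training_set(image_rois, novelty)$cv_set
  })

  cv <- NULL
  hp <- config$hyperparameter
  if (identical(hp, "auto")) {
    cv <- step("crossval", {
      run_cv(training, config$family, default_hp_grid(config$family),
             seed = .derive_seed(config$seed, 3L))
    })
    hp <- attr(cv$curve, "optimum")
    if (is.na(hp)) hp <- NULL
  }

  model <- step("train", {
    fit_classifier(config$family, hp, training,
                   seed = .derive_seed(config$seed, 4L))
  })

  pred <- step("predict", classify_volume(model, features, inputs$voi))

  mrf_res <- step("mrf-smooth", smooth_study(pred$probs, inputs$voi, config$mrf))

  summary <- step("summarize",
                  summarize_habitats(mrf_res$labels, inputs$adc, inputs$voi))

  recovery <- NULL
  if (config$mode == "phantom") {
    truth <- inputs$study$truth$labels
    sel <- !is.na(mrf_res$labels$labels) & !is.na(truth)
    recovery <- list(
      accuracy_raw = 100 * mean(pred$labels$labels[sel] == truth[sel]),
      accuracy_mrf = 100 * mean(mrf_res$labels$labels[sel] == truth[sel]))
  }

  report <- list(config = config,
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("habitatmap")),
                 stages = as.list(stages),
                 summary = summary,
                 labels_raw = pred$labels,
                 labels = mrf_res$labels,
                 probs = pred$probs,
                 selected_hyperparameter = hp,
                 cv = cv,
                 mrf = list(median_iterations = mrf_res$median_iterations,
                            all_converged = mrf_res$all_converged,
                            traces = mrf_res$traces),
                 recovery = recovery)
  class(report) <- "study_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    export_overlay(mrf_res$labels, NULL,
                   file.path(config$out_dir, "habitat_labels.nii.gz"),
                   file.path(config$out_dir, "legend.json"))
    write.csv(as.data.frame(summary),
              file.path(config$out_dir, "habitat_summary.csv"),
              row.names = FALSE)
    write_traces(mrf_res$traces, file.path(config$out_dir, "mrf_trace.csv"))
    meta <- list(seed = config$seed, family = config$family,
                 hyperparameter = hp, stages = as.list(stages),
                 package_version = report$package_version,
                 mrf_median_iterations = mrf_res$median_iterations,
                 recovery = recovery,
                 total_volume_mm3 = attr(summary, "total_volume_mm3"))
    jsonlite::write_json(meta, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("habitat-mapping study report\n")
  cat("  stages:", paste(names(x$stages), collapse = " -> "), "\n")
  if (!is.null(x$selected_hyperparameter)) {
    cat("  classifier:", x$config$family, "hyperparameter",
        signif(x$selected_hyperparameter, 4), "\n")
  } else {
    cat("  classifier:", x$config$family, "\n")
  }
  cat(sprintf("  MRF: median %.0f iteration(s), %s\n", x$mrf$median_iterations,
              if (x$mrf$all_converged) "all slices converged"
              else "NOT all slices converged"))
  if (!is.null(x$recovery)) {
    cat(sprintf("  phantom recovery: raw %.2f%%, MRF %.2f%%\n",
                x$recovery$accuracy_raw, x$recovery$accuracy_mrf))
  }
  print(x$summary)
  invisible(x)
}
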