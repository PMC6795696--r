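## Habitat quantification: per-class voxel counts, volumes, volume
## fractions and mean ADC; longitudinal deltas between timepoints; Spie
## chart geometry (segment angle = volume fraction, radius = mean ADC).

#' Summarize habitat composition within a VOI
#'
#' Volume fractions are voxel counts over the labeled VOI; mean ADC is
#' taken over class voxels with a valid ADC (in native mm^2/s). The
#' class-4 (fat) mean ADC is computed but flagged non-interpretable, since
#' ADC from fat-suppressed diffusion imaging is noise-dominated in fat.
#'
#' @param labels a `habitat_map`.
#' @param adc [parameter_volume()] tagged `"ADC mm^2/s"`.
#' @param voi [mask_volume()].
#' @return A `habitat_summary`: data.frame (one row per class 1-5) with
#'   `voxels`, `volume_mm3`, `fraction`, `mean_adc`, `adc_interpretable`;
#'   attributes `total_voxels`, `total_volume_mm3`, `voxel_volume_mm3`.
#' @export
summarize_habitats <- function(labels, adc, voi) {
  stopifnot(adc$quantity == "ADC mm^2/s")
  .stop_unless_aligned(labels, adc, voi)
  if (!any(voi$membership)) stop("VOI is empty")
  sel <- voi$membership & !is.na(labels$labels)
  if (!any(sel)) stop("no labeled voxels inside the VOI")
  lab <- labels$labels[sel]
  vox_vol <- prod(voi$grid$spacing)
  counts <- vapply(1:5, function(k) sum(lab == k), integer(1))
  total <- sum(counts)
  adc_vals <- adc$values[sel]
  adc_ok <- adc$valid[sel]
  mean_adc <- vapply(1:5, function(k) {
    v <- adc_vals[lab == k & adc_ok]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- data.frame(class_id = 1:5,
                    name = habitat_classes()$name,
                    voxels = counts,
                    volume_mm3 = counts * vox_vol,
                    fraction = counts / total,
                    mean_adc = mean_adc,
                    adc_interpretable = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  class(out) <- c("habitat_summary", "data.frame")
  attr(out, "total_voxels") <- total
  attr(out, "total_volume_mm3") <- total * vox_vol
  attr(out, "voxel_volume_mm3") <- vox_vol
  out
}

#' Spie-chart geometry for one or two habitat summaries
#'
#' A Spie chart is a pie-chart variant in which the angle of each segment
#' encodes the class's volume fraction and the segment radius its mean
#' ADC. When a reference (pre-treatment) summary is supplied, each segment
#' also carries the reference radius for the dashed overlay. Radii are
#' normalized to the largest interpretable class mean ADC across both
#' summaries so pre/post charts share one radial scale.
#'
#' @param summary a `habitat_summary`.
#' @param reference optional `habitat_summary` providing dashed radii.
#' @return data.frame with `class_id`, `color`, `angle_start`, `angle`
#'   (degrees, summing to 360 over classes present), `radius`,
#'   `ref_radius` (both on the normalized radial scale).
#' @export
spie_geometry <- function(summary, reference = NULL) {
  stopifnot(abs(sum(summary$fraction) - 1) < 1e-9)
  scale_pool <- summary$mean_adc[summary$adc_interpretable & summary$voxels > 0]
  if (!is.null(reference)) {
    scale_pool <- c(scale_pool,
                    reference$mean_adc[reference$adc_interpretable &
                                         reference$voxels > 0])
  }
  r_max <- if (length(scale_pool)) max(scale_pool, na.rm = TRUE) else 1
  angle <- 360 * summary$fraction
  data.frame(class_id = summary$class_id,
             color = habitat_classes()$color,
             angle_start = cumsum(c(0, angle[-length(angle)])),
             angle = angle,
             radius = summary$mean_adc / r_max,
             ref_radius = if (is.null(reference)) NA_real_
                          else reference$mean_adc / r_max)
}

#' Longitudinal habitat comparison
#'
#' Per-class changes in volume fraction and mean ADC between two
#' timepoints, plus the total tumor volume change in percent,
#' 100 (V_post - V_pre) / V_pre.
#'
#' @param pre,post `habitat_summary` objects from [summarize_habitats()].
#' @return A `longitudinal_comparison`: data.frame with per-class
#'   `delta_fraction`, `delta_mean_adc`, `pct_volume_change`; attribute
#'   `total_pct_volume_change`.
#' @export
compare_timepoints <- function(pre, post) {
  v_pre <- attr(pre, "total_volume_mm3")
  v_post <- attr(post, "total_volume_mm3")
  if (v_pre <= 0) stop("pre-treatment volume is zero")
  out <- data.frame(
    class_id = 1:5,
    delta_fraction = post$fraction - pre$fraction,
    delta_mean_adc = post$mean_adc - pre$mean_adc,
    pct_volume_change = ifelse(pre$volume_mm3 > 0,
                               100 * (post$volume_mm3 - pre$volume_mm3) /
                                 pre$volume_mm3, NA_real_),
    adc_delta_defined = !is.na(pre$mean_adc) & !is.na(post$mean_adc))
  class(out) <- c("longitudinal_comparison", "data.frame")
  attr(out, "total_pct_volume_change") <- 100 * (v_post - v_pre) / v_pre
  out
}

#' Export a color-coded habitat overlay
#'
#' Writes the label volume and a JSON color legend (class 1 red, 2 green,
#' 3 blue, 4 yellow, 5 gray) for overlay on anatomical images. The legend
#' always carries all five classes, even those absent from the map.
#'
#' @param labels a `habitat_map`.
#' @param anatomical optional [parameter_volume()]; must share the label
#'   grid (no resampling is performed).
#' @param path_labels output NIfTI path for the labels.
#' @param path_legend output JSON path for the legend.
#' @return Invisibly, the legend as a data.frame.
#' @export
export_overlay <- function(labels, anatomical = NULL,
                           path_labels, path_legend) {
  if (!is.null(anatomical)) .stop_unless_aligned(labels, anatomical)
  lab <- labels$labels
  lab[is.na(lab)] <- 0L
  img <- RNifti::asNifti(array(as.numeric(lab), dim = dim(lab)))
  RNifti::pixdim(img) <- labels$grid$spacing
  RNifti::writeNifti(img, path_labels, datatype = "uint8")
  legend <- habitat_classes()
  legend$present <- vapply(1:5, function(k) any(labels$labels == k, na.rm = TRUE),
                           logical(1))
  jsonlite::write_json(legend, path_legend, auto_unbox = TRUE, digits = NA)
  invisible(legend)
}

#' Draw a Spie chart
#'
#' Base-graphics rendering of [spie_geometry()]: wedge angle = volume
#' fraction, wedge radius = normalized mean ADC, dashed arcs = reference
#' (pre-treatment) radii.
#'
#' @param geometry output of [spie_geometry()].
#' @param main plot title.
#' @export
plot_spie <- function(geometry, main = "") {
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), axes = FALSE,
                 xlab = "", ylab = "", main = main, asp = 1)
  for (i in seq_len(nrow(geometry))) {
    if (geometry$angle[i] <= 0) next
    th <- seq(geometry$angle_start[i], geometry$angle_start[i] +
                geometry$angle[i], length.out = 64) * pi / 180
    r <- geometry$radius[i]
    if (is.na(r)) r <- 0
    graphics::polygon(c(0, r * cos(th)), c(0, r * sin(th)),
                      col = geometry$color[i], border = "white")
    if (!is.na(geometry$ref_radius[i])) {
      rr <- geometry$ref_radius[i]
      graphics::lines(rr * cos(th), rr * sin(th), lty = 2, lwd = 2)
    }
  }
  invisible(geometry)
}
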