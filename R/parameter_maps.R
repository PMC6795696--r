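## Parameter-map computation: fat fraction from Dixon signal pairs,
## enhancement fraction from pre/post-contrast T1 pairs, and the linear
## rescaling of (ADC, EF, FF) onto [0,1]^3 used for all classification.

#' Compute a Dixon fat-fraction map
#'
#' FF = S_fat / (S_fat + S_water) x 100, in percent. Voxels where either
#' signal is negative or invalid, or where the total signal is zero, are
#' masked invalid rather than given a fabricated value; the number of
#' rejected voxels is recorded in the `n_rejected` attribute.
#'
#' @param s_fat,s_water [parameter_volume()]s tagged `"signal a.u."` on one grid.
#' @return A [parameter_volume()] tagged `"FF %"`, values in \[0, 100\].
#' @export
compute_fat_fraction <- function(s_fat, s_water) {
  .check_signal_pair(s_fat, s_water)
  denom <- s_fat$values + s_water$values
  valid <- s_fat$valid & s_water$valid & is.finite(denom) & (denom > 0)
  ff <- array(NaN, dim = dim(denom))
  ff[valid] <- s_fat$values[valid] / denom[valid] * 100
  out <- parameter_volume(ff, spacing = s_fat$grid$spacing, quantity = "FF %",
                          valid = valid, label = "FF")
  attr(out, "n_rejected") <- sum(s_fat$valid | s_water$valid) - sum(valid)
  out
}

#' Compute a contrast enhancement-fraction map
#'
#' EF = (S_post - S_pre) / (S_post + S_pre) x 100, in percent, a
#' normalized measure of gadolinium uptake between the pre- and
#' post-contrast T1-weighted acquisitions. Zero-denominator and invalid
#' voxels are masked.
#'
#' @param s_pre,s_post [parameter_volume()]s tagged `"signal a.u."` on one grid.
#' @return A [parameter_volume()] tagged `"EF %"`, values in \[-100, 100\].
#' @export
compute_enhancement_fraction <- function(s_pre, s_post) {
  .check_signal_pair(s_pre, s_post)
  denom <- s_post$values + s_pre$values
  valid <- s_pre$valid & s_post$valid & is.finite(denom) & (denom > 0)
  ef <- array(NaN, dim = dim(denom))
  ef[valid] <- (s_post$values[valid] - s_pre$values[valid]) / denom[valid] * 100
  out <- parameter_volume(ef, spacing = s_pre$grid$spacing, quantity = "EF %",
                          valid = valid, label = "EF")
  attr(out, "n_rejected") <- sum(s_pre$valid | s_post$valid) - sum(valid)
  out
}

.check_signal_pair <- function(a, b) {
  for (v in list(a, b)) {
    if (!inherits(v, "parameter_volume")) stop("inputs must be parameter_volumes")
    if (v$quantity != "signal a.u.") {
      stop("expected quantity 'signal a.u.', got '", v$quantity, "'")
    }
  }
  .stop_unless_aligned(a, b)
}

#' Build the normalized 3-feature voxel field
#'
#' Applies the fixed linear rescalings ADC -> ADC / 3e-3 mm^2/s (clipped to
#' \[0, 1\]), EF -> (EF + 100) / 200 and FF -> FF / 100 so that every feature
#' lies in \[0, 1\]. A voxel yields a feature vector only where all three
#' source maps are valid. The quantity tags are checked strictly: passing a
#' map of the wrong quantity is a hard error, never a silent rescale.
#'
#' @param adc [parameter_volume()] tagged `"ADC mm^2/s"`.
#' @param ef [parameter_volume()] tagged `"EF %"`.
#' @param ff [parameter_volume()] tagged `"FF %"`.
#' @return A `feature_field`: list with 3-D arrays `adc_n`, `ef_n`, `ff_n`,
#'   a combined `valid` array and the shared `grid`.
#' @export
normalize_features <- function(adc, ef, ff) {
  if (adc$quantity != "ADC mm^2/s") stop("adc input tagged '", adc$quantity, "'")
  if (ef$quantity != "EF %") stop("ef input tagged '", ef$quantity, "'")
  if (ff$quantity != "FF %") stop("ff input tagged '", ff$quantity, "'")
  .stop_unless_aligned(adc, ef, ff)
  valid <- adc$valid & ef$valid & ff$valid
  adc_n <- pmin(pmax(adc$values / 3e-3, 0), 1)
  ef_n <- (ef$values + 100) / 200
  ff_n <- ff$values / 100
  structure(list(adc_n = adc_n, ef_n = ef_n, ff_n = ff_n,
                 valid = valid, grid = adc$grid),
            class = "feature_field")
}

#' @export
print.feature_field <- function(x, ...) {
  cat(sprintf("feature_field %s, %d valid voxels\n", format(x$grid), sum(x$valid)))
  invisible(x)
}

#' Extract feature rows from a field under a mask
#'
#' @param field a `feature_field` from [normalize_features()].
#' @param mask optional [mask_volume()]; defaults to all valid voxels.
#' @return Numeric matrix with columns `adc_n`, `ef_n`, `ff_n`, one row per
#'   voxel valid in all three maps and inside the mask, in raster
#'   (column-major) order.
#' @export
feature_matrix <- function(field, mask = NULL) {
  sel <- field$valid
  if (!is.null(mask)) {
    .stop_unless_aligned(field, mask)
    sel <- sel & mask$membership
  }
  cbind(adc_n = field$adc_n[sel], ef_n = field$ef_n[sel], ff_n = field$ff_n[sel])
}

#' Normalize raw (ADC, EF, FF) rows to the unit cube
#'
#' Row-wise version of [normalize_features()] for tabular data: ADC in
#' mm^2/s, EF and FF in percent.
#'
#' @param adc,ef,ff numeric vectors of equal length.
#' @return Matrix with columns `adc_n`, `ef_n`, `ff_n`.
#' @export
normalize_feature_rows <- function(adc, ef, ff) {
  stopifnot(length(adc) == length(ef), length(ef) == length(ff))
  cbind(adc_n = pmin(pmax(adc / 3e-3, 0), 1),
        ef_n = (ef + 100) / 200,
        ff_n = ff / 100)
}
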