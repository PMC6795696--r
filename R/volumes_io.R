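#' @useDynLib habitatmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd var t.test runif rnorm setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

## Recognized physical quantity tags for parameter volumes.
.QUANTITIES <- c("ADC mm^2/s", "FF %", "EF %", "signal a.u.", "normalized")

#' Voxel grid descriptor
#'
#' Shape, spacing and affine of a 3-D voxel grid. All volumes and masks
#' belonging to one study must share a single grid; no resampling is
#' performed anywhere in the package.
#'
#' @param shape integer length-3 vector (nx, ny, nz), all >= 1.
#' @param spacing numeric length-3 voxel spacing in mm, all > 0.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS affine built from `spacing`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, all(shape >= 1L),
            length(spacing) == 3, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "voxel_grid")
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("voxel_grid %dx%dx%d @ %.4gx%.4gx%.4g mm",
          x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

#' @export
print.voxel_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Scalar parameter volume
#'
#' A 3-D scalar field (ADC, fat-fraction, enhancement-fraction, raw signal or
#' normalized feature) on a voxel grid, with a validity mask. Non-finite
#' values are masked invalid, never imputed; raw signal volumes additionally
#' mask negative voxels.
#'
#' @param values 3-D numeric array.
#' @param spacing voxel spacing in mm (length 3).
#' @param quantity one of `"ADC mm^2/s"`, `"FF %"`, `"EF %"`,
#'   `"signal a.u."`, `"normalized"`.
#' @param valid optional logical array marking usable voxels; defaults to
#'   finite (and, for raw signals, non-negative) voxels.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @param label free-text label carried through to file outputs.
#' @return An object of class `parameter_volume`.
#' @export
parameter_volume <- function(values, spacing = c(1, 1, 1), quantity, valid = NULL,
                             affine = NULL, label = "") {
  quantity <- match.arg(quantity, .QUANTITIES)
  values <- as.array(values)
  if (length(dim(values)) != 3) {
    stop("parameter_volume requires a 3-D array, got ", length(dim(values)),
         " dimension(s)")
  }
  auto_valid <- is.finite(values)
  if (quantity == "signal a.u.") auto_valid <- auto_valid & (values >= 0)
  if (is.null(valid)) {
    valid <- auto_valid
  } else {
    stopifnot(identical(dim(valid), dim(values)))
    valid <- valid & auto_valid
  }
  if (!any(valid)) stop("volume has no valid voxels")
  structure(list(values = values,
                 valid = valid,
                 grid = voxel_grid(dim(values), spacing, affine),
                 quantity = quantity,
                 label = label),
            class = "parameter_volume")
}

#' @export
print.parameter_volume <- function(x, ...) {
  rng <- range(x$values[x$valid])
  cat(sprintf("parameter_volume [%s] %s\n  valid voxels: %d/%d, range [%.4g, %.4g]\n",
              x$quantity, format(x$grid), sum(x$valid), length(x$valid),
              rng[1], rng[2]))
  invisible(x)
}

#' Binary mask volume
#'
#' A boolean membership volume for a whole-tumor VOI or a training ROI,
#' on the same grid as the parameter volumes it indexes.
#'
#' @param membership logical (or 0/1) 3-D array.
#' @param spacing voxel spacing in mm.
#' @param label free-text identifier (VOI name or ROI id).
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(membership, spacing = c(1, 1, 1), label = "", affine = NULL) {
  membership <- as.array(membership)
  if (length(dim(membership)) != 3) stop("mask requires a 3-D array")
  storage.mode(membership) <- "logical"
  membership[is.na(membership)] <- FALSE
  structure(list(membership = membership,
                 grid = voxel_grid(dim(membership), spacing, affine),
                 label = label),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume '%s' %s, %d voxels set\n",
              x$label, format(x$grid), sum(x$membership)))
  invisible(x)
}

.grid_of <- function(x) {
  if (inherits(x, "voxel_grid")) x else x$grid
}

#' Read a parameter volume from NIfTI
#'
#' Reads a 3-D NIfTI-1 volume and tags it with the expected physical
#' quantity. Fails on non-3-D images or images with no finite voxel rather
#' than silently reinterpreting the data.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expected_quantity quantity tag to attach (see [parameter_volume()]).
#' @return A [parameter_volume()].
#' @export
read_volume <- function(path, expected_quantity) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4 && dm[4] == 1L) { dim(img) <- dm[1:3]; dm <- dm[1:3] }
  if (length(dm) != 3) {
    stop("expected a 3-D volume, got ", length(dm), " dimensions in ", path)
  }
  pd <- RNifti::pixdim(img)[1:3]
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  vals <- array(as.numeric(img), dim = dm)
  if (!any(is.finite(vals))) stop("volume contains no finite voxel values: ", path)
  parameter_volume(vals, spacing = pd, quantity = expected_quantity,
                   affine = aff, label = basename(path))
}

#' Write a parameter volume to NIfTI
#'
#' Invalid voxels are stored as NaN. The default `double` datatype makes a
#' write/read round trip bit-exact.
#'
#' @param vol a [parameter_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk datatype passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  vals <- vol$values
  vals[!vol$valid] <- NaN
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$grid$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 0/1 mask volume from NIfTI
#'
#' @param path path to a `.nii`/`.nii.gz` file with 0/1 voxel values.
#' @param label identifier attached to the mask.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4 && dm[4] == 1L) { dim(img) <- dm[1:3]; dm <- dm[1:3] }
  if (length(dm) != 3) stop("expected a 3-D mask, got ", length(dm), " dimensions")
  pd <- RNifti::pixdim(img)[1:3]
  mask_volume(array(as.numeric(img) != 0, dim = dm), spacing = pd, label = label)
}

#' Write a mask volume to NIfTI (0/1 valued)
#'
#' @param mask a [mask_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$membership),
                               dim = mask$grid$shape))
  RNifti::pixdim(img) <- mask$grid$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Check that volumes and masks share one voxel grid
#'
#' Grid equality is a hard precondition throughout the package (no spatial
#' registration or resampling is performed): shapes must match exactly and
#' spacings within an absolute tolerance.
#'
#' @param volumes list of [parameter_volume()] objects.
#' @param masks list of [mask_volume()] objects.
#' @param tol spacing tolerance in mm.
#' @return An `alignment_report`: list with `pass` (logical) and `mismatches`
#'   (character vector naming each failure).
#' @export
check_alignment <- function(volumes = list(), masks = list(), tol = 1e-4) {
  items <- c(volumes, masks)
  if (length(items) < 2) stop("check_alignment needs at least 2 inputs")
  labs <- vapply(seq_along(items), function(i) {
    lb <- items[[i]][["label"]]
    if (is.null(lb) || !nzchar(lb)) paste0("input", i) else lb
  }, character(1))
  ref <- .grid_of(items[[1]])
  mismatches <- character(0)
  for (i in seq_along(items)[-1]) {
    g <- .grid_of(items[[i]])
    if (!identical(g$shape, ref$shape)) {
      mismatches <- c(mismatches, sprintf(
        "%s: shape (%s) != (%s) of %s", labs[i],
        paste(g$shape, collapse = ","), paste(ref$shape, collapse = ","), labs[1]))
    }
    if (any(abs(g$spacing - ref$spacing) > tol)) {
      mismatches <- c(mismatches, sprintf(
        "%s: spacing (%s) differs from (%s) of %s by more than %g mm", labs[i],
        paste(signif(g$spacing, 8), collapse = ","),
        paste(signif(ref$spacing, 8), collapse = ","), labs[1], tol))
    }
  }
  structure(list(pass = length(mismatches) == 0L, mismatches = mismatches),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  if (x$pass) cat("alignment: PASS\n")
  else cat("alignment: FAIL\n ", paste(x$mismatches, collapse = "\n  "), "\n")
  invisible(x)
}

.stop_unless_aligned <- function(...) {
  rep <- check_alignment(list(...))
  if (!rep$pass) stop("grids not aligned: ", paste(rep$mismatches, collapse = "; "))
  invisible(TRUE)
}
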