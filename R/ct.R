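# Hounsfield-threshold CT volumetrics -----------------------------------

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of Hounsfield-unit intensities.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @return Object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be positive, length 1 or 3 (mm)")
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume %s voxels @ %s mm, HU range [%g, %g]>\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Segment a volume by Hounsfield thresholds
#'
#' A voxel is included iff `hu_low <= HU <= hu_high` (bounds inclusive)
#' and it is not covered by the exclusion mask.  The stock thresholds are
#' the bone-density window 225-3070 HU; the exclusion mask is how native
#' bone and heterotopic ossification, outlined upstream, are kept out of
#' the measurement.
#'
#' @param volume A [ct_volume()].
#' @param hu_low,hu_high Inclusive HU window; `hu_low < hu_high`.
#' @param exclusion Optional logical array of the same shape; `TRUE`
#'   voxels are excluded.
#' @return Logical array of included voxels.
#' @export
segment_hu <- function(volume, hu_low = 225, hu_high = 3070,
                       exclusion = NULL) {
  stopifnot(inherits(volume, "ct_volume"), hu_low < hu_high)
  mask <- volume$voxels >= hu_low & volume$voxels <= hu_high
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(volume$voxels)))
      stop("exclusion mask shape does not match the volume")
    mask <- mask & !exclusion
  }
  mask
}

#' Measure the volume of a voxel mask
#'
#' @param mask Logical array from [segment_hu()].
#' @param spacing Voxel spacing in mm (length 1 or 3), or a [ct_volume()]
#'   whose spacing to use.
#' @return Volume in mm^3 (`count * voxel volume`).
#' @export
measure_volume <- function(mask, spacing) {
  if (inherits(spacing, "ct_volume")) spacing <- spacing$spacing
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sum(mask) * prod(spacing)
}

#' Generate a synthetic Hounsfield volume with known inclusions
#'
#' Background sits below the bone window (default -50 HU); inclusions are
#' rasterized by voxel-center membership, and the analytic volume of each
#' is retained as ground truth.
#'
#' @param shape Integer length-3 array dimensions.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param inclusions List of inclusion descriptors: either
#'   `list(type = "sphere", center, radius, hu)` (center in voxel indices,
#'   radius in voxels) or `list(type = "box", lower, upper, hu)` (inclusive
#'   voxel index corners).
#' @param background_hu Background intensity, HU.
#' @return A [ct_volume()] with attribute `truth`: per-inclusion analytic
#'   volumes in mm^3 (spheres use the mm radius; boxes the exact voxel
#'   count).
#' @export
generate_hu_volume <- function(shape, spacing, inclusions = list(),
                               background_hu = -50) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0))
  spacing3 <- if (length(spacing) == 1L) rep(spacing, 3L) else as.numeric(spacing)
  vox <- array(background_hu, dim = shape)
  truth <- numeric(0)
  if (length(inclusions)) {
    ix <- slice.index(vox, 1); iy <- slice.index(vox, 2)
    iz <- slice.index(vox, 3)
    for (inc in inclusions) {
      if (identical(inc$type, "sphere")) {
        if (length(unique(spacing3)) != 1L)
          stop("sphere inclusions require isotropic spacing")
        cc <- inc$center
        inside <- (ix - cc[1])^2 + (iy - cc[2])^2 + (iz - cc[3])^2 <=
          inc$radius^2
        vox[inside] <- inc$hu
        truth <- c(truth, 4 / 3 * pi * (inc$radius * spacing3[1])^3)
      } else if (identical(inc$type, "box")) {
        lo <- inc$lower; hi <- inc$upper
        inside <- ix >= lo[1] & ix <= hi[1] & iy >= lo[2] & iy <= hi[2] &
          iz >= lo[3] & iz <= hi[3]
        vox[inside] <- inc$hu
        truth <- c(truth, sum(inside) * prod(spacing3))
      } else stop("unknown inclusion type")
    }
  }
  out <- ct_volume(vox, spacing3)
  attr(out, "truth") <- truth
  out
}

#' Read / write CT volumes as NIfTI
#'
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            RNifti::pixdim(img)[1:3])
}

#' @rdname read_ct_nifti
#' @param volume A [ct_volume()].
#' @export
write_ct_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
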