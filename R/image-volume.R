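# ImageVolume and VOIMask containers plus NIfTI I/O (via RNifti).

#' Construct an image volume
#'
#' A 3D scalar grid of body-weight-normalized standardized uptake values
#' (SUV) together with its voxel spacing in millimetres. This is the unit of
#' image I/O for the whole pipeline.
#'
#' @param data Numeric 3D array of finite, nonnegative values.
#' @param spacing_mm Positive numeric triple: in-plane pixel spacing and slice
#'   thickness, in mm. Default `c(2.73, 2.73, 3.27)`.
#' @param origin_mm Numeric triple, physical position of the first voxel
#'   corner; defaults to the grid origin.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm = c(2.73, 2.73, 3.27),
                         origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("SUV values must be finite and nonnegative", call. = FALSE)
  }
  spacing_mm <- assert_positive_triple(spacing_mm, "spacing_mm")
  structure(
    list(data = data, spacing_mm = spacing_mm, origin_mm = as.double(origin_mm)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, SUV range [%.3g, %.3g]\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Construct a volume-of-interest mask
#'
#' A boolean grid congruent with its parent volume marking the segmented
#' tumor; the physical volume in ml is derived from the voxel count and
#' spacing.
#'
#' @param mask Logical 3D array.
#' @param spacing_mm Positive numeric triple (mm).
#' @return An object of class `voi_mask` with a `volume_ml` field.
#' @export
voi_mask <- function(mask, spacing_mm) {
  if (!is.array(mask) || length(dim(mask)) != 3 || !is.logical(mask)) {
    stop("`mask` must be a logical 3D array", call. = FALSE)
  }
  spacing_mm <- assert_positive_triple(spacing_mm, "spacing_mm")
  structure(
    list(
      mask = mask, spacing_mm = spacing_mm,
      volume_ml = sum(mask) * prod(spacing_mm) / 1000
    ),
    class = "voi_mask"
  )
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf(
    "<voi_mask> %d voxels, %.3f ml (spacing %.2f x %.2f x %.2f mm)\n",
    sum(x$mask), x$volume_ml,
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]
  ))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()] with spacing taken from the header pixdim.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.double(img), dim = dim(img)),
               spacing_mm = abs(RNifti::pixdim(img))[1:3])
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written with 0/1 voxel values.
#'
#' @param x An [image_volume()] or [voi_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "voi_mask")) {
    arr <- array(as.double(x$mask), dim = dim(x$mask))
    spacing <- x$spacing_mm
  } else if (inherits(x, "image_volume")) {
    arr <- x$data
    spacing <- x$spacing_mm
  } else {
    stop("`x` must be an image_volume or voi_mask", call. = FALSE)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask
#'
#' @param path Path to a 0/1 NIfTI file.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  voi_mask(array(as.double(img) > 0.5, dim = dim(img)),
           spacing_mm = abs(RNifti::pixdim(img))[1:3])
}
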