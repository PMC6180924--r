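# Min-max quantization of a VOI into B grey-level bins.

#' Quantize a VOI into grey-level bins
#'
#' Levels are assigned by `min(B, floor((v - vmin) / (vmax - vmin) * B) + 1)`,
#' where vmin/vmax are the minimum and maximum SUV inside the mask, so the
#' darkest voxel maps to level 1 and the brightest to level B. A degenerate
#' VOI (vmax == vmin) maps entirely to level 1. Because the reference range
#' is internal, levels are invariant under any positive affine rescaling of
#' the SUVs.
#'
#' @param vol An [image_volume()].
#' @param mask A [voi_mask()] congruent with `vol` (nonempty).
#' @param B Number of bins, >= 2; default 64.
#' @return A `quantized_voi`: integer level array (0 outside the mask), the
#'   mask, B, vmin, vmax, spacing and voxel count.
#' @export
quantize <- function(vol, mask, B = 64) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(vol$data), dim(mask$mask))) {
    stop("volume and mask shapes differ", call. = FALSE)
  }
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  B <- as.integer(B)
  idx <- which(mask$mask)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  vals <- vol$data[idx]
  vmin <- min(vals)
  vmax <- max(vals)
  lev <- if (vmax > vmin) {
    pmin(B, as.integer(floor((vals - vmin) / (vmax - vmin) * B)) + 1L)
  } else {
    rep(1L, length(vals))
  }
  level_array <- array(0L, dim(mask$mask))
  level_array[idx] <- lev
  structure(
    list(
      level_array = level_array, mask = mask$mask, B = B,
      vmin = vmin, vmax = vmax, spacing_mm = mask$spacing_mm,
      n_voxels = length(idx)
    ),
    class = "quantized_voi"
  )
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat(sprintf("<quantized_voi> %d voxels, B = %d, SUV range [%.3g, %.3g]\n",
              x$n_voxels, x$B, x$vmin, x$vmax))
  invisible(x)
}
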