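# Semiautomatic tumor delineation: fractional SUVmax isocontour, connected
# component selection, physical volume and the small-volume exclusion rule.

#' Segment a lesion by fractional-SUVmax isocontour
#'
#' Thresholds the volume at `fraction * max(SUV)` (inclusive) and keeps the
#' connected component containing the global-maximum voxel, i.e. the whole
#' primary lesion. The threshold is relative, so segmentation is invariant
#' under positive rescaling of the volume.
#'
#' @param vol An [image_volume()].
#' @param fraction Threshold fraction of the global maximum, in (0, 1);
#'   default 0.40, the operator-independent clinical convention.
#' @param connectivity Component connectivity: 26 (default), 18 or 6.
#' @return A [voi_mask()].
#' @export
segment_isocontour <- function(vol, fraction = 0.40, connectivity = 26) {
  stopifnot(inherits(vol, "image_volume"))
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  mx <- max(vol$data)
  if (mx <= 0) {
    stop("volume has no positive uptake: cannot anchor an isocontour on SUVmax",
         call. = FALSE)
  }
  sel <- vol$data >= fraction * mx
  # ties for the maximum: which.max returns the lowest linear index, which is
  # the lexicographically smallest (z, y, x) voxel; all tied voxels are
  # in-threshold regardless
  anchor <- which.max(vol$data)
  comp <- label_components(sel, connectivity = connectivity)
  anchor_comp <- comp$membership[match(anchor, comp$index)]
  mask <- array(FALSE, dim(vol$data))
  mask[comp$index[comp$membership == anchor_comp]] <- TRUE
  voi_mask(mask, vol$spacing_mm)
}

#' Physical volume of a mask in millilitres
#'
#' `voxel count * dx * dy * dz / 1000`, exactly.
#'
#' @param mask A [voi_mask()], or a logical 3D array combined with
#'   `spacing_mm`.
#' @param spacing_mm Spacing triple (mm); ignored when `mask` is a
#'   [voi_mask()].
#' @return Volume in ml; an empty mask returns 0 with a warning.
#' @export
compute_volume_ml <- function(mask, spacing_mm = NULL) {
  if (inherits(mask, "voi_mask")) {
    n <- sum(mask$mask)
    spacing_mm <- mask$spacing_mm
  } else {
    n <- sum(mask)
    spacing_mm <- assert_positive_triple(spacing_mm, "spacing_mm")
  }
  if (n == 0) {
    warning("empty mask: volume is 0 ml")
    return(0)
  }
  n * prod(spacing_mm) / 1000
}

#' Partition subjects by the small-volume exclusion rule
#'
#' Tumors smaller than the threshold are excluded because texture features
#' become unstable (or undefined) on too few voxels; 2.6 ml is the volume of
#' the third-smallest NEMA IEC quality-assurance sphere (17 mm inner
#' diameter) to one decimal.
#'
#' @param masks Named list of [voi_mask()] objects (or a numeric vector of
#'   volumes in ml).
#' @param threshold_ml Exclusion threshold; subjects with volume strictly
#'   below it are excluded. Default 2.6.
#' @return A list with `retained` and `excluded` (character ids) and `table`,
#'   a data frame of id, volume_ml, retained flag and reason.
#' @export
apply_volume_filter <- function(masks, threshold_ml = 2.6) {
  vols <- if (is.numeric(masks)) {
    masks
  } else {
    vapply(masks, function(m) {
      if (inherits(m, "voi_mask")) m$volume_ml else compute_volume_ml(m)
    }, numeric(1))
  }
  ids <- names(vols) %||% as.character(seq_along(vols))
  if (is.null(names(vols))) names(vols) <- ids
  keep <- vols >= threshold_ml
  tab <- data.frame(
    id = ids,
    volume_ml = as.double(vols),
    retained = keep,
    reason = ifelse(keep, "",
                    sprintf("volume %.3f ml < %.1f ml", vols, threshold_ml)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(retained = ids[keep], excluded = ids[!keep], table = tab)
}
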