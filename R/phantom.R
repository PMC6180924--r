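# Synthetic PET-like tumor phantoms.
#
# A phantom is a spherical (optionally ellipsoidal) uptake lesion on a flat
# background: intensity = background + (peak - background) * profile(d),
# where profile is 1 inside the tumor radius and falls off as a Gaussian
# shoulder exp(-(d - r)^2 / (2 sigma^2)) outside it. border_sigma_mm = 0
# gives a sharp plateau ("spiculated-looking" phenotype), large sigma gives a
# smooth Gaussian-like uptake; this single knob drives the low-intensity
# long-run emphasis contrast between the two phenotypes.

#' Specify a tumor phantom
#'
#' @param grid_shape Integer triple: grid size in voxels.
#' @param spacing_mm Positive triple, voxel spacing in mm
#'   (default `c(2.73, 2.73, 3.27)`, a typical clinical PET reconstruction).
#' @param tumor_center_mm Real triple, lesion centre in physical mm
#'   coordinates (voxel centres sit at `(i - 0.5) * spacing`). Default: grid
#'   centre.
#' @param tumor_radius_mm Positive plateau radius in mm.
#' @param peak_suv Positive plateau uptake (SUV).
#' @param border_sigma_mm Nonnegative border falloff scale in mm; 0 = sharp
#'   binary plateau edge before noise.
#' @param background_suv Nonnegative background uptake.
#' @param noise_sd SD of additive Gaussian noise (truncated at 0).
#' @param axis_ratios Positive triple scaling the lesion axes (1,1,1 =
#'   sphere); distances are computed on coordinates divided by these ratios.
#' @param seed Integer seed for the noise, or NULL.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 24),
                         spacing_mm = c(2.73, 2.73, 3.27),
                         tumor_center_mm = NULL,
                         tumor_radius_mm = 12,
                         peak_suv = 12,
                         border_sigma_mm = 2,
                         background_suv = 1,
                         noise_sd = 0.5,
                         axis_ratios = c(1, 1, 1),
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  spacing_mm <- assert_positive_triple(spacing_mm, "spacing_mm")
  extent <- grid_shape * spacing_mm
  if (is.null(tumor_center_mm)) tumor_center_mm <- extent / 2
  stopifnot(
    length(tumor_center_mm) == 3,
    tumor_radius_mm > 0, peak_suv > 0,
    border_sigma_mm >= 0, background_suv >= 0, noise_sd >= 0
  )
  axis_ratios <- assert_positive_triple(axis_ratios, "axis_ratios")
  half_axes <- tumor_radius_mm * axis_ratios
  if (any(tumor_center_mm - half_axes < 0) ||
      any(tumor_center_mm + half_axes > extent)) {
    stop(sprintf(
      "tumor (centre %s mm, radius %.1f mm) does not fit inside the %s mm grid",
      paste(round(tumor_center_mm, 1), collapse = "x"), tumor_radius_mm,
      paste(round(extent, 1), collapse = "x")
    ), call. = FALSE)
  }
  structure(
    list(
      grid_shape = grid_shape, spacing_mm = spacing_mm,
      tumor_center_mm = as.double(tumor_center_mm),
      tumor_radius_mm = tumor_radius_mm, peak_suv = peak_suv,
      border_sigma_mm = border_sigma_mm, background_suv = background_suv,
      noise_sd = noise_sd, axis_ratios = axis_ratios, seed = seed
    ),
    class = "phantom_spec"
  )
}

#' Generate a PET-like tumor phantom
#'
#' Deterministic given `spec$seed`: the same spec and seed yield bit-identical
#' volumes.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_volume()] of size `spec$grid_shape`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  cx <- (seq_len(dims[1]) - 0.5) * spec$spacing_mm[1]
  cy <- (seq_len(dims[2]) - 0.5) * spec$spacing_mm[2]
  cz <- (seq_len(dims[3]) - 0.5) * spec$spacing_mm[3]
  dx2 <- ((cx - spec$tumor_center_mm[1]) / spec$axis_ratios[1])^2
  dy2 <- ((cy - spec$tumor_center_mm[2]) / spec$axis_ratios[2])^2
  dz2 <- ((cz - spec$tumor_center_mm[3]) / spec$axis_ratios[3])^2
  d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  r <- spec$tumor_radius_mm
  profile <- array(0, dims)
  inside <- d <= r
  profile[inside] <- 1
  if (spec$border_sigma_mm > 0) {
    out <- !inside
    profile[out] <- exp(-(d[out] - r)^2 / (2 * spec$border_sigma_mm^2))
  }
  vals <- spec$background_suv + (spec$peak_suv - spec$background_suv) * profile
  maybe_set_seed(spec$seed)
  if (spec$noise_sd > 0) {
    vals <- array(
      pmax(0, vals + stats::rnorm(prod(dims), sd = spec$noise_sd)), dims
    )
  }
  image_volume(vals, spacing_mm = spec$spacing_mm)
}
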