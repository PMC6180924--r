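# Scalar texture and first-order features. Quantized-domain features (GLRLM,
# GLCM, GLSZM, NGTDM, codes) operate on the 64-bin VOI; first-order and
# SUV/SUL peak operate on raw SUV.

#' Run percentage
#'
#' Number of runs divided by the maximal possible number of runs
#' (`n_directions * n_voxels`); values near 1 mean no collinear grey-level
#' repetition, low values mean long homogeneous stretches.
#'
#' @param m A `glrlm` from [glrlm_build()].
#' @return A value in (0, 1].
#' @export
run_percentage <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  sum(m$counts) / (m$n_directions * m$n_voxels)
}

#' Low-intensity long-run emphasis (LILRE)
#'
#' `(1/N_r) * sum_ij p(i,j) * j^2 / i^2`: long runs (j^2) of low grey levels
#' (1/i^2) dominate. High values indicate long strings of low-level voxels,
#' e.g. a broad dim shoulder around a lesion core.
#'
#' @param m A `glrlm`.
#' @return LILRE value (> 0).
#' @export
lilre <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  nr <- sum(m$counts)
  if (nr == 0) stop("empty run-length matrix", call. = FALSE)
  i2 <- (seq_len(nrow(m$counts)))^2
  j2 <- (seq_len(ncol(m$counts)))^2
  sum(m$counts * outer(1 / i2, j2)) / nr
}

#' GLCM homogeneity and contrast
#'
#' Homogeneity `sum P/(1+|i-j|)` and contrast `sum P*(i-j)^2` of the
#' normalized symmetric co-occurrence matrix.
#'
#' @param g A `glcm` from [glcm_build()], or a `quantized_voi` (the matrix is
#'   then built with the default 13 directions).
#' @return Named numeric vector `c(homogeneity=, contrast=)`; NA when the VOI
#'   has no voxel pairs.
#' @export
glcm_features <- function(g) {
  if (inherits(g, "quantized_voi")) g <- glcm_build(g)
  stopifnot(inherits(g, "glcm"))
  if (g$pairs == 0) {
    return(c(homogeneity = NA_real_, contrast = NA_real_))
  }
  i <- row(g$P)
  j <- col(g$P)
  c(
    homogeneity = sum(g$P / (1 + abs(i - j))),
    contrast = sum(g$P * (i - j)^2)
  )
}

#' NGTDM coarseness
#'
#' `1 / (eps + sum_i p_i * s_i)`; a locally uniform texture has tiny
#' neighbourhood deviations and hence large coarseness. `eps` caps the
#' constant-image case at `1/eps`.
#'
#' @param q A `quantized_voi` or an `ngtdm` from [ngtdm_build()].
#' @param eps Stabilizer, default 1e-6.
#' @return Coarseness value.
#' @export
ngtdm_coarseness <- function(q, eps = 1e-6) {
  m <- if (inherits(q, "ngtdm")) q else ngtdm_build(q)
  1 / (eps + sum(m$p * m$s))
}

#' GLSZM low-intensity large-zone emphasis (LILZE)
#'
#' `(1/N_z) * sum z(i,s) * s^2 / i^2` over 26-connected constant-level zones:
#' large zones of low grey level dominate.
#'
#' @param q A `quantized_voi` or a `glszm` from [glszm_build()].
#' @return LILZE value.
#' @export
glszm_lilze <- function(q) {
  m <- if (inherits(q, "glszm")) q else glszm_build(q)
  nz <- sum(m$counts)
  if (nz == 0) stop("empty size-zone matrix", call. = FALSE)
  i2 <- (seq_len(nrow(m$counts)))^2
  s2 <- (seq_len(ncol(m$counts)))^2
  sum(m$counts * outer(1 / i2, s2)) / nz
}

#' Texture-code similarity
#'
#' Probability that two distinct voxels drawn at random carry an identical
#' texture-unit code (the Simpson index of the code distribution):
#' `sum_c n_c (n_c - 1) / (N (N - 1))`.
#'
#' @param codes Character vector of codes from [texture_codes()] (or a
#'   `quantized_voi`, coded first).
#' @return A value in `[0, 1]`.
#' @export
code_similarity <- function(codes) {
  if (inherits(codes, "quantized_voi")) codes <- texture_codes(codes)
  n <- length(codes)
  if (n < 2) stop("code similarity needs at least 2 coded voxels", call. = FALSE)
  tab <- table(codes)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' First-order (histogram) features of a VOI
#'
#' Mean and maximum SUV, plus moment skewness `m3/m2^{3/2}` and Pearson
#' kurtosis `m4/m2^2` (not excess) from central moments over the mask voxels.
#' A zero-variance VOI yields NA skewness/kurtosis with a warning.
#'
#' @param vol An [image_volume()].
#' @param mask A [voi_mask()].
#' @return Named vector: SUVmean, SUVmax, skewness, kurtosis.
#' @export
first_order_features <- function(vol, mask) {
  vals <- vol$data[mask$mask]
  if (!length(vals)) stop("mask is empty", call. = FALSE)
  m <- mean(vals)
  out <- c(SUVmean = m, SUVmax = max(vals),
           skewness = NA_real_, kurtosis = NA_real_)
  if (length(vals) >= 2) {
    d <- vals - m
    m2 <- mean(d^2)
    if (m2 > 0) {
      out["skewness"] <- mean(d^3) / m2^1.5
      out["kurtosis"] <- mean(d^4) / m2^2
    } else {
      warning("zero-variance VOI: skewness/kurtosis undefined")
    }
  }
  out
}

#' SUV peak: maximal 1 cm^3 sphere-mean uptake
#'
#' For every mask voxel, the mean SUV over grid voxels whose centres lie
#' within the 1 cm^3 sphere (radius `(3/(4*pi))^(1/3)` cm) centred on it;
#' SUV peak is the maximum of these sphere means. At coarse spacing the
#' sphere may contain a single voxel, in which case SUV peak equals SUVmax.
#'
#' @param vol An [image_volume()].
#' @param mask A [voi_mask()].
#' @return SUV peak.
#' @export
suv_peak <- function(vol, mask) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "voi_mask"))
  dims <- dim(vol$data)
  sp <- vol$spacing_mm
  r_mm <- 10 * (3 / (4 * pi))^(1 / 3)
  reach <- floor(r_mm / sp)
  offs <- as.matrix(expand.grid(
    ox = -reach[1]:reach[1], oy = -reach[2]:reach[2], oz = -reach[3]:reach[3]
  ))
  d2 <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2
  offs <- offs[d2 <= r_mm^2, , drop = FALSE]
  acc <- array(0, dims)
  cnt <- array(0L, dims)
  for (k in seq_len(nrow(offs))) {
    r <- shift_ranges(dims, offs[k, ])
    if (is.null(r)) next
    acc[r$center[[1]], r$center[[2]], r$center[[3]]] <-
      acc[r$center[[1]], r$center[[2]], r$center[[3]]] +
      vol$data[r$neighbor[[1]], r$neighbor[[2]], r$neighbor[[3]]]
    cnt[r$center[[1]], r$center[[2]], r$center[[3]]] <-
      cnt[r$center[[1]], r$center[[2]], r$center[[3]]] + 1L
  }
  max((acc / cnt)[mask$mask])
}

#' Lean body mass by the James formula
#'
#' Male: `1.10 W - 128 (W/H)^2`; female: `1.07 W - 148 (W/H)^2`, with weight
#' W in kg and height H in cm.
#'
#' @param weight_kg,height_cm Anthropometrics.
#' @param sex "M" or "F" (vectorized).
#' @return Lean body mass in kg.
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex) {
  male <- toupper(as.character(sex)) == "M"
  ifelse(male,
         1.10 * weight_kg - 128 * (weight_kg / height_cm)^2,
         1.07 * weight_kg - 148 * (weight_kg / height_cm)^2)
}

#' SUL peak from SUV peak and anthropometrics
#'
#' `SUL_peak = SUV_peak * LBM / weight`; with missing anthropometrics the
#' result is NA (SUV peak itself is still available).
#'
#' @param suv_peak_value SUV peak.
#' @param weight_kg,height_cm,sex Anthropometrics (vectorized).
#' @return SUL peak (NA where anthropometrics are missing).
#' @export
sul_peak <- function(suv_peak_value, weight_kg, height_cm, sex) {
  ok <- !(is.na(weight_kg) | is.na(height_cm) | is.na(sex))
  out <- rep(NA_real_, length(ok))
  lbm <- lean_body_mass(weight_kg[ok], height_cm[ok], sex[ok])
  out[ok] <- suv_peak_value * lbm / weight_kg[ok]
  out
}

#' Extract the full feature vector of a segmented VOI
#'
#' Computes first-order features and SUV peak on raw SUV, and all
#' quantized-domain texture features on the B-bin min-max quantized VOI.
#' Features that are undefined on a degenerate VOI (e.g. zero variance) are
#' reported as NA rather than raising an error. The extraction is
#' deterministic.
#'
#' @param vol An [image_volume()].
#' @param mask A [voi_mask()] that passed the volume filter.
#' @param B Quantization bins (default 64).
#' @param aggregation GLRLM aggregation: `"sum"` (default; matrices of the 13
#'   directions summed before feature computation) or `"average"`
#'   (per-direction feature values averaged).
#' @param anthro Optional list/row with `weight_kg`, `height_cm`, `sex` for
#'   SUL peak; when NULL, SUL_peak is NA.
#' @param eps Coarseness stabilizer (default 1e-6).
#' @return Named numeric vector: SUVmean, SUVmax, skewness, kurtosis,
#'   SUV_peak, SUL_peak, GLCM_homogeneity, GLCM_contrast, run_percentage,
#'   LILRE, coarseness, code_similarity, LILZE, volume_ml. The quantization
#'   and neighbourhood settings are attached as the `"config"` attribute.
#' @export
extract_features <- function(vol, mask, B = 64,
                             aggregation = c("sum", "average"),
                             anthro = NULL, eps = 1e-6) {
  aggregation <- match.arg(aggregation)
  fo <- suppressWarnings(first_order_features(vol, mask))
  q <- quantize(vol, mask, B = B)
  dirs <- scan_directions()
  if (aggregation == "sum") {
    m <- glrlm_build(q, dirs)
    rp <- run_percentage(m)
    li <- lilre(m)
  } else {
    per <- lapply(seq_len(nrow(dirs)), function(k) {
      glrlm_build(q, dirs[k, , drop = FALSE])
    })
    rp <- mean(vapply(per, run_percentage, numeric(1)))
    li <- mean(vapply(per, lilre, numeric(1)))
  }
  gl <- glcm_features(q)
  cs <- if (q$n_voxels >= 2) code_similarity(q) else NA_real_
  sp <- suv_peak(vol, mask)
  slp <- if (is.null(anthro)) NA_real_ else {
    sul_peak(sp, anthro$weight_kg, anthro$height_cm,
             anthro$sex %||% anthro$gender)
  }
  out <- c(
    SUVmean = unname(fo["SUVmean"]), SUVmax = unname(fo["SUVmax"]),
    skewness = unname(fo["skewness"]), kurtosis = unname(fo["kurtosis"]),
    SUV_peak = sp, SUL_peak = slp,
    GLCM_homogeneity = unname(gl["homogeneity"]),
    GLCM_contrast = unname(gl["contrast"]),
    run_percentage = rp, LILRE = li,
    coarseness = ngtdm_coarseness(q, eps = eps),
    code_similarity = cs,
    LILZE = glszm_lilze(q),
    volume_ml = mask$volume_ml
  )
  attr(out, "config") <- list(
    B = B, connectivity = 26, n_directions = nrow(dirs),
    aggregation = aggregation, eps = eps
  )
  out
}
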