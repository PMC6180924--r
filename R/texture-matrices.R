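# Texture matrix builders on a quantized VOI: grey-level run-length (GLRLM),
# co-occurrence (GLCM), size-zone (GLSZM), neighbourhood grey-tone difference
# (NGTDM) and texture-spectrum codes. Definitions are explicit so each
# builder can be checked against exhaustive brute-force enumeration.

#' Build a grey-level run-length matrix
#'
#' For each scan direction, maximal runs of collinear in-mask voxels sharing
#' a grey level are counted; runs break at the mask boundary. With the
#' default direction set the matrices of the 13 unique 3D directions are
#' summed. The partition identity `sum_ij p(i,j) * j = n_directions * n_voxels`
#' always holds.
#'
#' @param q A `quantized_voi` from [quantize()].
#' @param directions Integer matrix of direction vectors (rows); default the
#'   13 unique directions of the 26-neighbourhood.
#' @return A `glrlm` object: `counts` (levels x run length), `n_directions`,
#'   `n_voxels`.
#' @export
glrlm_build <- function(q, directions = scan_directions()) {
  stopifnot(inherits(q, "quantized_voi"))
  directions <- matrix(as.integer(directions), ncol = 3)
  dims <- dim(q$level_array)
  L <- as.integer(q$level_array)
  nvox <- prod(dims)
  x <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  y <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  z <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  maxlen <- max(dims)
  B <- q$B
  counts <- matrix(0, nrow = B, ncol = maxlen)
  base <- 2L * (dims[1] + dims[2] + dims[3]) + 3L
  for (k in seq_len(nrow(directions))) {
    d <- directions[k, ]
    t <- if (d[1] != 0) x else if (d[2] != 0) y else z
    # unwind the coordinates by t*d: constant along each scan line
    k1 <- x - t * d[1]
    k2 <- y - t * d[2]
    k3 <- z - t * d[3]
    key <- ((k1 + base) * base + (k2 + base)) * base + (k3 + base)
    ord <- order(key, t)
    lv <- L[ord]
    ko <- key[ord]
    # every grid voxel is enumerated, so positions along a line are
    # consecutive; a new run starts at a line break or level change
    newrun <- c(TRUE, ko[-1] != ko[-nvox] | lv[-1] != lv[-nvox])
    runlen <- tabulate(cumsum(newrun))
    runlev <- lv[newrun]
    inmask <- runlev > 0L
    if (any(inmask)) {
      cell <- (runlen[inmask] - 1L) * B + runlev[inmask]
      counts <- counts + matrix(tabulate(cell, nbins = B * maxlen), nrow = B)
    }
  }
  # trim all-zero trailing run-length columns (keep at least one)
  last <- max(1L, max(which(colSums(counts) > 0), 1L))
  structure(
    list(counts = counts[, seq_len(last), drop = FALSE],
         n_directions = nrow(directions), n_voxels = q$n_voxels),
    class = "glrlm"
  )
}

#' Build a symmetric grey-level co-occurrence matrix
#'
#' Counts ordered pairs of in-mask voxels at displacement 1 over the scan
#' directions, symmetrized (both orders counted) and normalized to sum to 1.
#'
#' @inheritParams glrlm_build
#' @return A `glcm` object: `P` (normalized B x B matrix), `pairs` (raw count).
#' @export
glcm_build <- function(q, directions = scan_directions()) {
  stopifnot(inherits(q, "quantized_voi"))
  directions <- matrix(as.integer(directions), ncol = 3)
  dims <- dim(q$level_array)
  B <- q$B
  tab <- matrix(0, B, B)
  for (k in seq_len(nrow(directions))) {
    r <- shift_ranges(dims, directions[k, ])
    if (is.null(r)) next
    a1 <- q$level_array[r$center[[1]], r$center[[2]], r$center[[3]]]
    a2 <- q$level_array[r$neighbor[[1]], r$neighbor[[2]], r$neighbor[[3]]]
    ok <- a1 > 0L & a2 > 0L
    if (!any(ok)) next
    cell <- (a2[ok] - 1L) * B + a1[ok]
    m <- matrix(tabulate(cell, nbins = B * B), nrow = B)
    tab <- tab + m + t(m)
  }
  total <- sum(tab)
  structure(
    list(P = if (total > 0) tab / total else tab, pairs = total, B = B),
    class = "glcm"
  )
}

#' Build a grey-level size-zone matrix
#'
#' Zones are 26-connected components of constant grey level inside the mask;
#' `z(i, s)` counts zones of level i and size s. The partition identity
#' `sum z(i,s) * s = n_voxels` always holds.
#'
#' @param q A `quantized_voi`.
#' @param connectivity Zone connectivity (default 26).
#' @return A `glszm` object: `counts` (levels x zone size), `n_voxels`.
#' @export
glszm_build <- function(q, connectivity = 26) {
  stopifnot(inherits(q, "quantized_voi"))
  B <- q$B
  maxsize <- q$n_voxels
  cells <- integer(0)
  for (lev in sort(unique(q$level_array[q$mask]))) {
    comp <- label_components(q$level_array == lev, connectivity = connectivity)
    sizes <- tabulate(comp$membership)
    cells <- c(cells, (sizes - 1L) * B + as.integer(lev))
  }
  counts <- matrix(tabulate(cells, nbins = B * maxsize), nrow = B)
  last <- max(1L, max(which(colSums(counts) > 0), 1L))
  structure(
    list(counts = counts[, seq_len(last), drop = FALSE], n_voxels = q$n_voxels),
    class = "glszm"
  )
}

#' Build a neighbourhood grey-tone difference table
#'
#' For each occurring level i: the occurrence probability `p_i` among voxels
#' with at least one in-mask 26-neighbour, and the summed absolute deviation
#' `s_i` of the level from the mean level of the voxel's in-mask neighbours.
#' Neighbourhoods are truncated at the mask boundary; voxels with no in-mask
#' neighbour are skipped.
#'
#' @param q A `quantized_voi`.
#' @return An `ngtdm` object: vectors `p` and `s` indexed by level 1..B, and
#'   `n_valid`, the number of contributing voxels.
#' @export
ngtdm_build <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  dims <- dim(q$level_array)
  L <- q$level_array
  nb_sum <- array(0, dims)
  nb_cnt <- array(0L, dims)
  offs <- neighbor_offsets()
  for (off_row in seq_len(nrow(offs))) {
    off <- offs[off_row, ]
    r <- shift_ranges(dims, off)
    if (is.null(r)) next
    sub <- L[r$neighbor[[1]], r$neighbor[[2]], r$neighbor[[3]]]
    inm <- sub > 0L
    nb_sum[r$center[[1]], r$center[[2]], r$center[[3]]] <-
      nb_sum[r$center[[1]], r$center[[2]], r$center[[3]]] + sub * inm
    nb_cnt[r$center[[1]], r$center[[2]], r$center[[3]]] <-
      nb_cnt[r$center[[1]], r$center[[2]], r$center[[3]]] + inm
  }
  valid <- q$mask & nb_cnt > 0L
  lev <- L[valid]
  dev <- abs(lev - nb_sum[valid] / nb_cnt[valid])
  B <- q$B
  n_i <- tabulate(lev, nbins = B)
  s_i <- numeric(B)
  agg <- rowsum(dev, group = lev)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  n_valid <- sum(n_i)
  structure(
    list(p = if (n_valid > 0) n_i / n_valid else n_i, s = s_i,
         n_valid = n_valid, B = B),
    class = "ngtdm"
  )
}

#' Texture-spectrum codes of a quantized VOI
#'
#' Each in-mask voxel is coded by comparing its level to its 26 neighbours in
#' a fixed order: 0 if the neighbour is strictly lower, 1 if equal, 2 if
#' strictly higher; neighbours outside the grid or the mask are coded as
#' equal. The code is the concatenated 26-digit ternary word.
#'
#' @param q A `quantized_voi`.
#' @return Character vector of codes, one per mask voxel.
#' @export
texture_codes <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  dims <- dim(q$level_array)
  idx <- which(q$mask)
  n <- length(idx)
  coord <- arrayInd(idx, dims)
  center_lev <- q$level_array[idx]
  offs <- neighbor_offsets()
  digits <- matrix(1L, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[k, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nidx <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    nl <- q$level_array[nidx]
    cl <- center_lev[ok]
    d <- rep(1L, length(nl))
    d[nl > 0L & nl < cl] <- 0L
    d[nl > 0L & nl > cl] <- 2L
    digits[ok, k] <- d
  }
  do.call(paste0, as.data.frame(digits))
}
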