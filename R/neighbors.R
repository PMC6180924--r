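# 3D neighbourhood machinery: scan directions, neighbour offsets and
# connected-component labeling. Everything downstream (segmentation, texture
# matrices) is built on these primitives.

#' Unique 3D scan directions
#'
#' The 13 unique displacement vectors of the 26-neighbourhood (one per
#' antipodal pair), used for run-length and co-occurrence scanning. With
#' `connectivity = 18` the 4 corner directions are dropped, with
#' `connectivity = 6` only the 3 axis directions remain.
#'
#' @param connectivity One of 26 (default), 18 or 6.
#' @return An integer matrix with one direction per row and columns dx, dy, dz.
#' @export
scan_directions <- function(connectivity = 26) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(d != 0) > 0, , drop = FALSE]
  keep <- d[, 1] > 0 | (d[, 1] == 0 & d[, 2] > 0) |
    (d[, 1] == 0 & d[, 2] == 0 & d[, 3] > 0)
  d <- d[keep, , drop = FALSE]
  ord <- rowSums(abs(d))
  if (connectivity == 26) {
    sel <- rep(TRUE, nrow(d))
  } else if (connectivity == 18) {
    sel <- ord <= 2
  } else if (connectivity == 6) {
    sel <- ord == 1
  } else {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  unname(as.matrix(d[sel, , drop = FALSE]))
}

# All offsets of the chosen neighbourhood (both antipodal partners), in a
# fixed row order; texture-spectrum codes depend on this order being stable.
neighbor_offsets <- function(connectivity = 26) {
  d <- scan_directions(connectivity)
  rbind(d, -d)
}

# Index ranges pairing each voxel with its neighbour at `off`; returns NULL
# when the offset shifts the whole grid out of bounds.
shift_ranges <- function(dims, off) {
  r <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1L, 1L - off[a])
    hi <- min(dims[a], dims[a] - off[a])
    if (lo > hi) return(NULL)
    r[[a]] <- lo:hi
  }
  list(center = r, neighbor = lapply(1:3, function(a) r[[a]] + off[a]))
}

#' Label connected components of a voxel set
#'
#' @param sel Logical 3D array marking the voxel set.
#' @param connectivity 26 (default), 18 or 6.
#' @return A list with `index` (linear indices of the set voxels) and
#'   `membership` (integer component label per set voxel).
#' @keywords internal
label_components <- function(sel, connectivity = 26) {
  dims <- dim(sel)
  stopifnot(length(dims) == 3)
  idx <- which(sel)
  n <- length(idx)
  if (n == 0) return(list(index = integer(0), membership = integer(0)))
  lookup <- integer(prod(dims))
  lookup[idx] <- seq_len(n)
  coord <- arrayInd(idx, dims)
  dirs <- scan_directions(connectivity)
  from <- integer(0)
  to <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    nb <- coord + matrix(dirs[k, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nidx <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    hit <- lookup[nidx] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, lookup[nidx[hit]])
  }
  if (length(from) == 0) {
    membership <- seq_len(n)
  } else {
    g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
    membership <- as.integer(igraph::components(g)$membership)
  }
  list(index = idx, membership = membership)
}
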