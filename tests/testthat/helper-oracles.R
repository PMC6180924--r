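# Brute-force enumeration oracles for the texture matrix builders, written
# as plain nested loops with their own neighbourhood enumeration so they are
# independent of the package internals. All take an integer level array with
# 0 marking out-of-mask voxels.

bf_in_bounds <- function(x, y, z, dims) {
  x >= 1 && x <= dims[1] && y >= 1 && y <= dims[2] && z >= 1 && z <= dims[3]
}

# the 13 antipodal-unique displacement vectors, enumerated longhand
bf_directions <- function() {
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0)) {
      out <- rbind(out, c(dx, dy, dz))
    }
  }
  out
}

bf_offsets26 <- function() {
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (!(dx == 0 && dy == 0 && dz == 0)) out <- rbind(out, c(dx, dy, dz))
  }
  out
}

bf_glrlm <- function(L, dirs = bf_directions(), B = max(L)) {
  dims <- dim(L)
  counts <- matrix(0, B, max(dims))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      lev <- L[x, y, z]
      if (lev == 0) next
      px <- x - d[1]; py <- y - d[2]; pz <- z - d[3]
      if (bf_in_bounds(px, py, pz, dims) && L[px, py, pz] == lev) next
      len <- 1
      nx <- x + d[1]; ny <- y + d[2]; nz <- z + d[3]
      while (bf_in_bounds(nx, ny, nz, dims) && L[nx, ny, nz] == lev) {
        len <- len + 1
        nx <- nx + d[1]; ny <- ny + d[2]; nz <- nz + d[3]
      }
      counts[lev, len] <- counts[lev, len] + 1
    }
  }
  counts
}

bf_glcm <- function(L, dirs = bf_directions(), B = max(L)) {
  dims <- dim(L)
  tab <- matrix(0, B, B)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      i <- L[x, y, z]
      if (i == 0) next
      nx <- x + d[1]; ny <- y + d[2]; nz <- z + d[3]
      if (!bf_in_bounds(nx, ny, nz, dims)) next
      j <- L[nx, ny, nz]
      if (j == 0) next
      tab[i, j] <- tab[i, j] + 1
      tab[j, i] <- tab[j, i] + 1
    }
  }
  if (sum(tab) > 0) tab / sum(tab) else tab
}

bf_glszm <- function(L, B = max(L)) {
  dims <- dim(L)
  offs <- bf_offsets26()
  seen <- array(FALSE, dims)
  counts <- matrix(0, B, sum(L > 0))
  for (x0 in 1:dims[1]) for (y0 in 1:dims[2]) for (z0 in 1:dims[3]) {
    lev <- L[x0, y0, z0]
    if (lev == 0 || seen[x0, y0, z0]) next
    stack <- list(c(x0, y0, z0))
    seen[x0, y0, z0] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        nx <- v[1] + offs[k, 1]; ny <- v[2] + offs[k, 2]; nz <- v[3] + offs[k, 3]
        if (bf_in_bounds(nx, ny, nz, dims) && !seen[nx, ny, nz] &&
            L[nx, ny, nz] == lev) {
          seen[nx, ny, nz] <- TRUE
          stack[[length(stack) + 1]] <- c(nx, ny, nz)
        }
      }
    }
    counts[lev, size] <- counts[lev, size] + 1
  }
  counts
}

bf_ngtdm <- function(L, B = max(L)) {
  dims <- dim(L)
  offs <- bf_offsets26()
  n_i <- numeric(B)
  s_i <- numeric(B)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    lev <- L[x, y, z]
    if (lev == 0) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
      if (bf_in_bounds(nx, ny, nz, dims) && L[nx, ny, nz] > 0) {
        nb <- c(nb, L[nx, ny, nz])
      }
    }
    if (length(nb) == 0) next
    n_i[lev] <- n_i[lev] + 1
    s_i[lev] <- s_i[lev] + abs(lev - mean(nb))
  }
  list(p = if (sum(n_i) > 0) n_i / sum(n_i) else n_i, s = s_i,
       n_valid = sum(n_i))
}

# texture-unit codes; own offset order, compared via the partition into
# identical-code groups (invariant to any fixed digit ordering)
bf_codes <- function(L) {
  dims <- dim(L)
  offs <- bf_offsets26()
  codes <- character(0)
  for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
    cl <- L[x, y, z]
    if (cl == 0) next
    dig <- integer(nrow(offs))
    for (k in seq_len(nrow(offs))) {
      nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
      dig[k] <- if (!bf_in_bounds(nx, ny, nz, dims) || L[nx, ny, nz] == 0) {
        1L
      } else if (L[nx, ny, nz] < cl) 0L else if (L[nx, ny, nz] > cl) 2L else 1L
    }
    codes <- c(codes, paste(dig, collapse = ""))
  }
  codes
}

bf_code_similarity <- function(codes) {
  n <- length(codes)
  tab <- table(codes)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

# random masked quantized VOI fixture
random_qvoi <- function(seed, dims = c(4, 4, 4), B = 4, p_mask = 0.7) {
  set.seed(seed)
  vol <- image_volume(array(runif(prod(dims)), dims), spacing_mm = c(1, 1, 1))
  repeat {
    m <- array(runif(prod(dims)) < p_mask, dims)
    if (sum(m) >= 3) break
  }
  quantize(vol, voi_mask(m, c(1, 1, 1)), B = B)
}

# pad two count matrices to common size before comparison
pad_counts <- function(a, b) {
  nr <- max(nrow(a), nrow(b))
  nc <- max(ncol(a), ncol(b))
  grow <- function(m) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  list(a = grow(a), b = grow(b))
}
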