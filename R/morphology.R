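# Internal 3D array utilities: shifts, 3x3x3 filters, connectivity.
# All operations work in voxel units on plain R arrays; no physical spacing
# enters here (spacing matters only for the phantom PSF).

# Shifted copy: out[x,y,z] = a[x+s1, y+s2, z+s3], `fill` where out of bounds.
shift3d <- function(a, s, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  lo <- pmax(1L, 1L - s)
  hi <- pmin(d, d - s)
  if (any(hi < lo)) return(out)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    a[(lo[1] + s[1]):(hi[1] + s[1]),
      (lo[2] + s[2]):(hi[2] + s[2]),
      (lo[3] + s[3]):(hi[3] + s[3])]
  out
}

kernel_offsets_27 <- function() {
  as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

# 3x3x3 box (mean) filter, zero-padded borders.
mean_filter3 <- function(a) {
  offs <- kernel_offsets_27()
  acc <- array(0, dim(a))
  for (i in seq_len(nrow(offs))) acc <- acc + shift3d(a, offs[i, ], fill = 0)
  acc / 27
}

# Grayscale erosion with the 3x3x3 structuring element; voxels outside the
# grid do not constrain the minimum (fill = +Inf).
erode_gray3 <- function(a) {
  offs <- kernel_offsets_27()
  acc <- shift3d(a, offs[1, ], fill = Inf)
  for (i in 2:nrow(offs)) acc <- pmin(acc, shift3d(a, offs[i, ], fill = Inf))
  acc
}

# Binary erosion with the 3x3x3 structuring element; outside the grid is
# background, so voxels on the grid border always erode away.
erode_binary3 <- function(mask) {
  offs <- kernel_offsets_27()
  acc <- shift3d(mask, offs[1, ], fill = FALSE)
  for (i in 2:nrow(offs)) acc <- acc & shift3d(mask, offs[i, ], fill = FALSE)
  acc
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26L) {
    offs <- kernel_offsets_27()
    offs[rowSums(offs != 0) > 0, , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26")
  }
}

coord_to_index <- function(p, d) {
  (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
}

# Connected component of `mask` containing `seed` (voxel coordinate c(x,y,z),
# 1-based), by breadth-first frontier expansion. Returns a logical array.
flood_fill <- function(mask, seed, connectivity = 26L) {
  d <- dim(mask)
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > d)) stop("seed outside grid")
  si <- coord_to_index(seed, d)
  if (!mask[si]) stop("seed voxel is not inside the mask")
  flood_fill_idx(mask, si, connectivity)
}

# Same, from one or more linear seed indices.
flood_fill_idx <- function(mask, seed_idx, connectivity = 26L) {
  d <- dim(mask)
  offs <- neighbor_offsets(as.integer(connectivity))
  visited <- array(FALSE, d)
  visited[seed_idx] <- TRUE
  frontier <- seed_idx
  plane <- d[1] * d[2]
  while (length(frontier)) {
    fc <- arrayInd(frontier, d)
    cand <- integer(0)
    for (i in seq_len(nrow(offs))) {
      nx <- fc[, 1] + offs[i, 1]
      ny <- fc[, 2] + offs[i, 2]
      nz <- fc[, 3] + offs[i, 3]
      ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
      if (any(ok)) {
        cand <- c(cand, (nz[ok] - 1L) * plane + (ny[ok] - 1L) * d[1] + nx[ok])
      }
    }
    cand <- unique(cand)
    cand <- cand[mask[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# Fill cavities: voxels of the complement not 6-connected to the grid
# border become part of the mask.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(bg & border)
  if (!length(seeds)) return(array(TRUE, d))
  outside <- flood_fill_idx(bg, seeds, connectivity = 6L)
  !outside
}

round_half_up <- function(x) floor(x + 0.5)
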