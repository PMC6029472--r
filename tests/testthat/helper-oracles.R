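# Independent brute-force oracles, deliberately written as plain nested
# loops so they share no code with the implementation they check.

# Central-difference gradient magnitude times weight image, zero outside
# the grid, computed voxel by voxel.
oracle_iwg <- function(bins, weights, mask) {
  d <- dim(bins)
  g <- array(0, d)
  at <- function(a, x, y, z) {
    if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) 0 else a[x, y, z]
  }
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    gx <- (at(bins, x + 1, y, z) - at(bins, x - 1, y, z)) / 2
    gy <- (at(bins, x, y + 1, z) - at(bins, x, y - 1, z)) / 2
    gz <- (at(bins, x, y, z + 1) - at(bins, x, y, z - 1)) / 2
    g[x, y, z] <- sqrt(gx^2 + gy^2 + gz^2) * weights[x, y, z]
  }
  g[!mask] <- 0
  g
}

# Depth-first flood fill with an explicit stack and shuffled neighbor
# order, to confirm the result is traversal-order independent.
oracle_flood <- function(mask, seed, connectivity = 6L, shuffle_seed = 1) {
  d <- dim(mask)
  offs <- if (connectivity == 6L) {
    list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    o <- expand.grid(-1:1, -1:1, -1:1)
    o <- o[rowSums(o != 0) > 0, ]
    lapply(seq_len(nrow(o)), function(i) as.integer(o[i, ]))
  }
  set.seed(shuffle_seed)
  visited <- array(FALSE, d)
  stack <- list(as.integer(seed))
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in sample(offs)) {
      q <- p + o
      if (all(q >= 1) && all(q <= d) && mask[q[1], q[2], q[3]] &&
          !visited[q[1], q[2], q[3]]) {
        visited[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
  }
  visited
}

# 3x3x3 mean filter (zero padding) and grayscale minimum filter
# (out-of-grid ignored), voxel by voxel.
oracle_smooth_erode <- function(a) {
  d <- dim(a)
  sm <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    s <- 0
    for (i in -1:1) for (j in -1:1) for (k in -1:1) {
      xx <- x + i; yy <- y + j; zz <- z + k
      if (xx >= 1 && yy >= 1 && zz >= 1 && xx <= d[1] && yy <= d[2] && zz <= d[3])
        s <- s + a[xx, yy, zz]
    }
    sm[x, y, z] <- s / 27
  }
  er <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    m <- Inf
    for (i in -1:1) for (j in -1:1) for (k in -1:1) {
      xx <- x + i; yy <- y + j; zz <- z + k
      if (xx >= 1 && yy >= 1 && zz >= 1 && xx <= d[1] && yy <= d[2] && zz <= d[3])
        m <- min(m, sm[xx, yy, zz])
    }
    er[x, y, z] <- m
  }
  list(smoothed = sm, eroded = er)
}

# Exact Mann-Whitney p by enumerating every group assignment.
oracle_mw_exact <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cmb <- utils::combn(n, na)
  U <- apply(cmb, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(U <= U_obs), mean(U >= U_obs)))
}

# Small solid test volume: cuboid of value `inside` on background `outside`.
make_box_volume <- function(d = c(12, 12, 12), lo = c(4, 4, 4), hi = c(9, 9, 9),
                            inside = 4, outside = 1, spacing = c(1, 1, 1)) {
  a <- array(outside, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inside
  suv_volume(a, spacing = spacing)
}
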