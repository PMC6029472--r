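make_lesion <- function(values) {
  # 1D strip of values embedded in a 3D volume, lesion mask over the strip
  n <- length(values)
  a <- array(0, c(n, 3, 3))
  a[, 2, 2] <- values
  m <- array(FALSE, c(n, 3, 3))
  m[, 2, 2] <- TRUE
  list(vol = suv_volume(a), m1 = voi_mask(m))
}

test_that("redigitization maps min to 0, max to 15, halves rounding up", {
  L <- make_lesion(c(2.5, 5.0, 7.5))
  rd <- redigitize(L$vol, L$m1)
  expect_identical(rd$data[, 2, 2], c(0L, 8L, 15L))
  expect_equal(rd$source_min, 2.5)
  expect_equal(rd$source_max, 7.5)
  expect_true(all(rd$data[!L$m1$data] == 0))
})

test_that("redigitized bins are invariant under positive affine rescaling", {
  set.seed(5)
  vals <- runif(40, 2.5, 9)
  L <- make_lesion(vals)
  rd <- redigitize(L$vol, L$m1)
  for (ab in list(c(2, 0), c(0.5, 1), c(3.7, 0.2))) {
    L2 <- make_lesion(ab[1] * vals + ab[2])
    rd2 <- redigitize(L2$vol, L2$m1)
    expect_identical(rd2$data, rd$data)
  }
})

test_that("a constant lesion cannot be redigitized", {
  L <- make_lesion(rep(4, 5))
  expect_error(redigitize(L$vol, L$m1), "degenerate lesion")
})

test_that("gradient is zero on constant interiors and unit on a ramp", {
  # constant bins, constant SUV: interior gradient must vanish
  a <- array(4, c(7, 7, 7))
  m <- voi_mask(array(TRUE, c(7, 7, 7)))
  v <- suv_volume(a)
  rd <- structure(list(data = array(7L, c(7, 7, 7)), source_min = 0,
                       source_max = 1), class = "redig_volume")
  g <- intensity_weighted_gradient(rd, v, m)
  expect_equal(g$data[4, 4, 4], 0)

  # one-bin-per-voxel ramp along x at SUV 4: interior |gradient| = 1
  bins <- array(0L, c(7, 7, 7))
  for (x in 1:7) bins[x, , ] <- x
  rd2 <- structure(list(data = bins, source_min = 0, source_max = 1),
                   class = "redig_volume")
  g2 <- intensity_weighted_gradient(rd2, v, m)
  expect_equal(g2$data[4, 4, 4], 1 * 4)
})

test_that("intensity-weighted gradient matches a brute-force loop", {
  for (s in 1:5) {
    set.seed(s)
    d <- c(5, 5, 5)
    mask <- array(runif(prod(d)) > 0.3, d)
    bins <- array(0L, d)
    bins[mask] <- sample(0:15, sum(mask), replace = TRUE)
    suv <- array(runif(prod(d), 0, 10), d)
    v <- suv_volume(suv)
    rd <- structure(list(data = bins, source_min = 0, source_max = 15),
                    class = "redig_volume")
    g <- intensity_weighted_gradient(rd, v, voi_mask(mask))
    expect_equal(g$data, oracle_iwg(bins, suv, mask))
  }
})

test_that("smoothing and erosion match brute force and bound each other", {
  set.seed(9)
  a <- array(runif(7^3, 0, 5), c(7, 7, 7))
  g <- structure(list(data = a, stage = "raw"), class = "gradient_volume")
  out <- smooth_then_erode(g)
  orc <- oracle_smooth_erode(a)
  expect_equal(out$data, orc$eroded)
  expect_true(all(out$data <= orc$smoothed + 1e-12))

  # constant field is a fixed point in the interior
  cg <- structure(list(data = array(2, c(7, 7, 7)), stage = "raw"),
                  class = "gradient_volume")
  expect_equal(smooth_then_erode(cg)$data[4, 4, 4], 2)

  # a single spike spreads to 27 voxels then collapses back near zero
  sp <- array(0, c(7, 7, 7)); sp[4, 4, 4] <- 27
  spo <- oracle_smooth_erode(sp)
  expect_equal(sum(spo$smoothed > 0), 27)
  spg <- structure(list(data = sp, stage = "raw"), class = "gradient_volume")
  expect_equal(smooth_then_erode(spg)$data, spo$eroded)
  # only the spike voxel itself keeps a fully-covered neighborhood
  expect_equal(sum(smooth_then_erode(spg)$data > 0), 1)
})

test_that("seed selection takes the masked minimum with lexicographic ties", {
  d <- c(6, 6, 6)
  g <- structure(list(data = array(5, d), stage = "eroded"),
                 class = "gradient_volume")
  g$data[3, 4, 5] <- 0.1
  mask <- voi_mask(array(TRUE, d))
  expect_equal(find_seed(g, mask), c(3L, 4L, 5L))

  g$data[3, 4, 5] <- 5
  g$data[1, 1, 1] <- 1; g$data[2, 1, 1] <- 1  # tie: x=1 wins (first in array order)
  expect_equal(find_seed(g, mask), c(1L, 1L, 1L))
  expect_error(find_seed(g, voi_mask(array(FALSE, d))), "empty region")
})

test_that("region growing equals flood fill and ignores traversal order", {
  # threshold 0: zero plateau only
  d <- c(8, 8, 8)
  gv <- array(1, d); gv[3:5, 3:5, 3:5] <- 0
  g <- structure(list(data = gv, stage = "eroded"), class = "gradient_volume")
  m1 <- voi_mask(array(TRUE, d))
  core <- grow_necrotic_core(g, c(4, 4, 4), m1)
  expect_equal(mask_n(core), 27)
  expect_true(core$data[4, 4, 4])

  # uniform g: everything within the lesion qualifies
  gu <- structure(list(data = array(2, d), stage = "eroded"),
                  class = "gradient_volume")
  expect_equal(mask_n(grow_necrotic_core(gu, c(1, 1, 1), m1)), prod(d))

  # random instances against the DFS oracle with shuffled neighbor order
  for (s in 1:10) {
    set.seed(s)
    gv <- array(runif(prod(d), 0, 3), d)
    mk <- array(runif(prod(d)) > 0.25, d)
    seedpt <- c(sample(8, 1), sample(8, 1), sample(8, 1))
    mk[seedpt[1], seedpt[2], seedpt[3]] <- TRUE
    g <- structure(list(data = gv, stage = "eroded"), class = "gradient_volume")
    core <- grow_necrotic_core(g, seedpt, voi_mask(mk))
    thr <- 3 * gv[seedpt[1], seedpt[2], seedpt[3]]
    oracle <- oracle_flood(mk & (gv <= thr), seedpt, connectivity = 6L,
                           shuffle_seed = s + 100)
    expect_identical(core$data, oracle)
    expect_true(core$data[seedpt[1], seedpt[2], seedpt[3]])
  }
})

test_that("metabolism means are plain bin averages with empty-VOI errors", {
  L <- make_lesion(c(2.5, 5.0, 7.5))
  rd <- redigitize(L$vol, L$m1)
  expect_equal(core_metabolism(rd, L$m1), mean(c(0, 8, 15)))
  one <- array(FALSE, dim(rd$data)); one[1, 2, 2] <- TRUE
  expect_equal(core_metabolism(rd, voi_mask(one)), 0)
  expect_error(core_metabolism(rd, voi_mask(array(FALSE, dim(rd$data)))),
               "empty region")
})

test_that("shell thickness follows the cube-root rule with a floor of 1", {
  expect_equal(shell_thickness(1000), 1L)
  expect_equal(shell_thickness(8000), 2L)
  expect_equal(shell_thickness(125), 1L)   # 0.5 rounds up, also the floor
  expect_equal(shell_thickness(27), 1L)    # 0.3 rounds to 0, clamped
  expect_equal(shell_thickness(15625), 3L) # 25 * 0.1 = 2.5 -> 3
  expect_error(shell_thickness(0), "empty region")
})

test_that("surface shell and eroded mask partition the lesion", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  m1 <- voi_mask(cube)
  sv <- surface_voi(m1, 1)
  expect_equal(mask_n(sv$m2), 27)
  expect_equal(mask_n(sv$surface), 125 - 27)
  expect_false(any(sv$surface$data & sv$m2$data))
  expect_identical(sv$surface$data | sv$m2$data, cube)

  small <- array(FALSE, c(5, 5, 5)); small[2:4, 2:4, 2:4] <- TRUE
  sv3 <- surface_voi(voi_mask(small), 1)
  expect_equal(mask_n(sv3$m2), 1)
  expect_equal(mask_n(sv3$surface), 26)

  expect_warning(svk <- surface_voi(m1, 5), "extinguished")
  expect_equal(mask_n(svk$m2), 0)
  expect_identical(svk$surface$data, cube)
})

test_that("full pipeline output satisfies the mask set algebra", {
  ph <- generate_phantom(phantom_spec("hollow_ball", grid_shape = c(48, 48, 48),
                                      tumor_radii = 45, core_radii = 20,
                                      rng_seed = 21))
  res <- compute_ratio(ph$volume, c(24, 24, 40))
  expect_false(any(res$surface_voi$data & res$m2$data))
  expect_identical(res$surface_voi$data | res$m2$data, res$lesion_voi$data)
  expect_true(all(res$lesion_voi$data[res$core_voi$data]))
  expect_equal(res$n, mask_n(res$lesion_voi))
  expect_equal(res$ratio, res$surface_metabolism / res$core_metabolism)
  expect_gte(res$k, 1)
  expect_true(res$core_metabolism >= 0 && res$core_metabolism <= 15)
  expect_true(res$surface_metabolism >= 0 && res$surface_metabolism <= 15)
})

test_that("benign-style phantoms keep surface and core metabolism close", {
  ph <- generate_phantom(phantom_spec("diffuse_high", grid_shape = c(48, 48, 48),
                                      tumor_radii = 45, rng_seed = 8))
  res <- compute_ratio(ph$volume, c(24, 24, 24))
  expect_lt(abs(res$surface_metabolism - res$core_metabolism) /
              res$core_metabolism, 0.2)
  ph2 <- generate_phantom(phantom_spec("hollow_ball", grid_shape = c(48, 48, 48),
                                       tumor_radii = 45, core_radii = 20,
                                       rng_seed = 8))
  res2 <- compute_ratio(ph2$volume, c(24, 24, 40))
  expect_lt(res2$core_metabolism, res2$surface_metabolism)
})
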