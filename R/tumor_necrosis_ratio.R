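#' Redigitize lesion intensities into 16 equally spaced bins
#'
#' Voxel SUVs inside the lesion mask are linearly mapped to the integer
#' levels 0..15, with the minimum in-lesion SUV mapped to 0 and the maximum
#' to 15; halves round up. Voxels outside the mask are 0. The resulting bins
#' are invariant under any positive affine rescaling of the input volume.
#'
#' @param vol an [suv_volume()].
#' @param m1 lesion [voi_mask()].
#' @return An object of class `redig_volume`: integer array `data` plus the
#'   `source_min`/`source_max` SUVs used for scaling.
#' @export
redigitize <- function(vol, m1) {
  stopifnot(inherits(vol, "suv_volume"), inherits(m1, "voi_mask"))
  if (!any(m1$data)) stop("empty region: lesion mask is empty")
  vals <- vol$data[m1$data]
  mn <- min(vals); mx <- max(vals)
  if (mx <= mn)
    stop("degenerate lesion: constant intensity, cannot redigitize")
  bins <- array(0L, dim(vol$data))
  bins[m1$data] <- as.integer(round_half_up((vals - mn) / (mx - mn) * 15))
  structure(list(data = bins, source_min = mn, source_max = mx),
            class = "redig_volume")
}

#' Intensity-weighted gradient magnitude image
#'
#' The 3D gradient of the redigitized image is taken by central differences
#' in voxel units (voxels outside the lesion contribute bin value 0), its
#' Euclidean magnitude is multiplied voxelwise by the original SUV image,
#' and the result is zeroed outside the lesion. The image is low where
#' tissue is both homogeneous and photopenic, which is what characterizes a
#' necrotic core.
#'
#' @param redig a `redig_volume` from [redigitize()].
#' @param vol the original [suv_volume()].
#' @param m1 lesion [voi_mask()].
#' @return An object of class `gradient_volume` (fields `data`, `stage`),
#'   stage `"raw"`.
#' @export
intensity_weighted_gradient <- function(redig, vol, m1) {
  stopifnot(inherits(redig, "redig_volume"), inherits(vol, "suv_volume"),
            inherits(m1, "voi_mask"))
  r <- redig$data
  if (!identical(dim(r), dim(vol$data)) || !identical(dim(r), dim(m1$data)))
    stop("shape mismatch between redigitized image, volume, and mask")
  storage.mode(r) <- "double"
  gx <- (shift3d(r, c(1, 0, 0)) - shift3d(r, c(-1, 0, 0))) / 2
  gy <- (shift3d(r, c(0, 1, 0)) - shift3d(r, c(0, -1, 0))) / 2
  gz <- (shift3d(r, c(0, 0, 1)) - shift3d(r, c(0, 0, -1))) / 2
  g <- sqrt(gx^2 + gy^2 + gz^2) * vol$data
  g[!m1$data] <- 0
  structure(list(data = g, stage = "raw"), class = "gradient_volume")
}

#' Smooth and erode the gradient image
#'
#' A 3x3x3 averaging (box) filter with zero-padded borders, followed by one
#' grayscale erosion (3x3x3 minimum filter; out-of-grid voxels do not
#' constrain the minimum).
#'
#' @param g a `gradient_volume` at stage `"raw"`.
#' @return A `gradient_volume` at stage `"eroded"`.
#' @export
smooth_then_erode <- function(g) {
  stopifnot(inherits(g, "gradient_volume"))
  if (!identical(g$stage, "raw")) stop("expected a raw gradient image")
  out <- erode_gray3(mean_filter3(g$data))
  structure(list(data = out, stage = "eroded"), class = "gradient_volume")
}

#' Locate the region-growing seed
#'
#' The seed is the voxel with the minimal intensity-weighted gradient value
#' within the search mask; ties resolve to the smallest linear array index.
#'
#' @param g a `gradient_volume`.
#' @param search_mask a nonempty [voi_mask()].
#' @return voxel coordinate `c(x, y, z)`, 1-based.
#' @export
find_seed <- function(g, search_mask) {
  stopifnot(inherits(g, "gradient_volume"), inherits(search_mask, "voi_mask"))
  idx <- which(search_mask$data)
  if (!length(idx)) stop("empty region: seed search mask is empty")
  as.integer(arrayInd(idx[which.min(g$data[idx])], dim(g$data)))
}

#' Grow the necrotic core from the seed
#'
#' The necrotic core VOI is the 6-connected component, within the lesion
#' mask, of voxels whose gradient value is at most three times the seed's
#' value (inclusive), containing the seed. The result is independent of
#' traversal order.
#'
#' @param g a `gradient_volume` (the smoothed + eroded image in the standard
#'   pipeline).
#' @param seed voxel coordinate `c(x, y, z)` inside the lesion.
#' @param m1 lesion [voi_mask()].
#' @return A [voi_mask()] with role `"necrotic_core"`; always contains the
#'   seed.
#' @export
grow_necrotic_core <- function(g, seed, m1) {
  stopifnot(inherits(g, "gradient_volume"), inherits(m1, "voi_mask"))
  seed <- as.integer(seed)
  d <- dim(g$data)
  if (!m1$data[coord_to_index(seed, d)])
    stop("seed must lie inside the lesion mask")
  thr <- 3 * g$data[coord_to_index(seed, d)]
  eligible <- m1$data & (g$data <= thr)
  voi_mask(flood_fill(eligible, seed, connectivity = 6L),
           role = "necrotic_core")
}

#' Mean redigitized intensity over a VOI
#'
#' `core_metabolism` is the mean bin value over the necrotic core VOI;
#' `surface_metabolism` the mean over the surface tumor VOI. Both lie in
#' `[0, 15]`.
#'
#' @param redig a `redig_volume`.
#' @param voi a nonempty [voi_mask()].
#' @return scalar mean bin value.
#' @export
core_metabolism <- function(redig, voi) {
  stopifnot(inherits(redig, "redig_volume"), inherits(voi, "voi_mask"))
  if (!any(voi$data)) stop("empty region: VOI contains no voxels")
  mean(redig$data[voi$data])
}

#' @rdname core_metabolism
#' @export
surface_metabolism <- core_metabolism

#' Surface-shell thickness from lesion size
#'
#' k = n^(1/3) * 0.1, rounded to the nearest integer (halves away from
#' zero) and clamped to at least 1, where n is the number of voxels in the
#' lesion VOI. The cube root makes k proportional to the lesion's linear
#' extent, so the shell thickness scales with lesion size.
#'
#' @param n lesion voxel count (>= 1).
#' @return integer erosion count k >= 1.
#' @export
shell_thickness <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("empty region: lesion voxel count must be >= 1")
  max(1L, as.integer(round_half_up(n^(1/3) * 0.1)))
}

#' Surface tumor VOI by repeated binary erosion
#'
#' M2 is the lesion mask eroded k times with the 3x3x3 structuring element;
#' the surface tumor VOI is the set difference M1 \ M2. If erosion
#' extinguishes the mask (M2 empty) the surface equals M1 and a warning is
#' raised.
#'
#' @param m1 lesion [voi_mask()].
#' @param k number of erosions (>= 1), from [shell_thickness()].
#' @return list with `surface` (role `"surface"`) and `m2` (role
#'   `"eroded_lesion"`), satisfying surface U M2 = M1 and surface ^ M2 = 0.
#' @export
surface_voi <- function(m1, k) {
  stopifnot(inherits(m1, "voi_mask"), k >= 1)
  if (!any(m1$data)) stop("empty region: lesion mask is empty")
  m2 <- m1$data
  for (i in seq_len(k)) m2 <- erode_binary3(m2)
  if (!any(m2))
    warning("erosion extinguished the lesion; surface VOI equals the lesion")
  list(surface = voi_mask(m1$data & !m2, role = "surface"),
       m2 = voi_mask(m2, role = "eroded_lesion"))
}

#' Metabolic tumor/necrosis ratio for one lesion
#'
#' Runs the full pipeline: lesion segmentation at the SUV threshold,
#' redigitization into 16 bins, intensity-weighted gradient, 3x3x3 smoothing
#' plus one grayscale erosion, seed at the gradient minimum (the search is
#' restricted to the lesion mask binary-eroded once, so edge-artifact voxels
#' cannot seed the core), 6-connected region growing at three times the seed
#' intensity, shell extraction, and finally
#'
#'   ratio = surface tumor metabolism / necrotic core metabolism.
#'
#' A ratio near 1 indicates a metabolically homogeneous (benign-type)
#' lesion; an elevated ratio indicates a photopenic necrotic core inside an
#' avid rim, the "hollow ball" phenotype of coagulative tumor necrosis.
#'
#' @param vol an [suv_volume()].
#' @param approx_point approximate lesion coordinate `c(x, y, z)`, 1-based.
#' @param suv_threshold lesion threshold; default 2.5.
#' @param snap_radius see [segment_lesion()].
#' @return An object of class `tnr_result`: `ratio`, `surface_metabolism`,
#'   `core_metabolism`, `k`, `n`, `seed`, `suv_max`, the masks
#'   (`lesion_voi`, `m2`, `surface_voi`, `core_voi`), and
#'   `core_surface_overlap`, the fraction of core voxels that also lie in
#'   the surface shell (eccentric cores may touch the boundary).
#' @export
compute_ratio <- function(vol, approx_point, suv_threshold = 2.5,
                          snap_radius = 20) {
  m1 <- segment_lesion(vol, approx_point, threshold = suv_threshold,
                       snap_radius = snap_radius)
  n <- mask_n(m1)
  redig <- redigitize(vol, m1)
  g <- smooth_then_erode(intensity_weighted_gradient(redig, vol, m1))

  search <- erode_binary3(m1$data)
  if (!any(search)) {
    warning("lesion too thin to erode; seed search uses the full lesion mask")
    search <- m1$data
  }
  seed <- find_seed(g, voi_mask(search, role = "eroded_lesion"))
  core <- grow_necrotic_core(g, seed, m1)

  k <- shell_thickness(n)
  sv <- surface_voi(m1, k)
  surf_met <- surface_metabolism(redig, sv$surface)
  core_met <- core_metabolism(redig, core)
  if (core_met == 0) {
    cond <- structure(
      list(message = "undefined ratio: necrotic core metabolism is 0",
           call = sys.call(), surface_metabolism = surf_met,
           core_voi = core, lesion_voi = m1, seed = seed),
      class = c("tnr_undefined_ratio", "error", "condition"))
    stop(cond)
  }
  structure(list(
    ratio = surf_met / core_met,
    surface_metabolism = surf_met,
    core_metabolism = core_met,
    k = k, n = n, seed = seed,
    suv_max = suv_max(vol, m1),
    lesion_voi = m1, m2 = sv$m2, surface_voi = sv$surface, core_voi = core,
    core_surface_overlap = sum(core$data & sv$surface$data) / mask_n(core)
  ), class = "tnr_result")
}

#' @export
print.tnr_result <- function(x, ...) {
  cat("Metabolic tumor/necrosis ratio\n")
  cat(sprintf("  ratio                 %.3f\n", x$ratio))
  cat(sprintf("  surface metabolism    %.3f (mean bin, 0-15)\n",
              x$surface_metabolism))
  cat(sprintf("  core metabolism       %.3f (mean bin, 0-15)\n",
              x$core_metabolism))
  cat(sprintf("  SUVmax                %.2f\n", x$suv_max))
  cat(sprintf("  lesion voxels n       %d  (shell thickness k = %d)\n",
              x$n, x$k))
  cat(sprintf("  seed voxel (x,y,z)    %s\n", paste(x$seed, collapse = ",")))
  cat(sprintf("  core voxels           %d (overlap with shell %.1f%%)\n",
              mask_n(x$core_voi), 100 * x$core_surface_overlap))
  invisible(x)
}
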