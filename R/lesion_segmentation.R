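#' Segment the lesion VOI (mask M1) at an SUV threshold
#'
#' Semiautomatic lesion delineation: the mask M1 is the 26-connected
#' component of the supra-threshold voxels (SUV >= `threshold`, inclusive)
#' that contains the operator-supplied approximate point. If the supplied
#' point itself is below threshold it is snapped to the nearest
#' supra-threshold voxel (Euclidean distance in voxel units, ties broken by
#' linear array order, i.e. x fastest).
#'
#' A lesion with a photopenic necrotic center has supra-threshold voxels
#' only in its rim; the volume of interest is nevertheless the solid
#' lesion, so enclosed cavities (background regions not 6-connected to the
#' grid border) are filled by default. Without this the necrotic core would
#' fall outside the VOI and its metabolism could not be measured.
#'
#' @param vol an [suv_volume()].
#' @param approx_point voxel coordinate `c(x, y, z)`, 1-based, inside the
#'   grid; an approximate click on the lesion.
#' @param threshold SUV threshold defining lesion tissue; default 2.5.
#' @param snap_radius maximum allowed distance (voxels) between
#'   `approx_point` and the nearest supra-threshold voxel; default 20.
#' @param fill_holes fill enclosed sub-threshold cavities; default TRUE.
#' @param bbox optional restriction against adjacent FDG-avid structures
#'   (e.g. bladder): a list with voxel corners `lo` and `hi`; voxels
#'   outside the box are excluded before the component search.
#' @return A [voi_mask()] with role `"lesion"`. Attribute `"seed"` carries
#'   the (possibly snapped) in-lesion point used.
#' @export
segment_lesion <- function(vol, approx_point, threshold = 2.5,
                           snap_radius = 20, fill_holes = TRUE,
                           bbox = NULL) {
  stopifnot(inherits(vol, "suv_volume"))
  d <- dim(vol$data)
  p <- as.integer(round(approx_point))
  if (length(p) != 3L || any(p < 1L) || any(p > d))
    stop("`approx_point` must be a voxel coordinate inside the grid")
  supra <- vol$data >= threshold
  if (!is.null(bbox)) {
    lo <- pmax(1L, as.integer(bbox$lo)); hi <- pmin(d, as.integer(bbox$hi))
    inbox <- array(FALSE, d)
    inbox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    supra <- supra & inbox
  }
  if (!any(supra))
    stop("no lesion: no voxel reaches the SUV threshold ", threshold)
  if (!supra[coord_to_index(p, d)]) {
    sc <- arrayInd(which(supra), d)
    dist2 <- (sc[, 1] - p[1])^2 + (sc[, 2] - p[2])^2 + (sc[, 3] - p[3])^2
    best <- which.min(dist2)   # first minimum = smallest linear index
    if (sqrt(dist2[best]) > snap_radius)
      stop("seed mismatch: nearest supra-threshold voxel is ",
           sprintf("%.1f", sqrt(dist2[best])), " voxels from `approx_point`",
           " (limit ", snap_radius, ")")
    p <- as.integer(sc[best, ])
  }
  m1 <- flood_fill(supra, p, connectivity = 26L)
  if (fill_holes) m1 <- fill_holes3(m1)
  out <- voi_mask(m1, role = "lesion")
  attr(out, "seed") <- p
  out
}
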