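#' SUV volume
#'
#' A 3D grid of standardized uptake values (SUV) with voxel spacing. SUV is
#' dimensionless: tissue activity concentration normalized by injected dose
#' per body weight. All voxel coordinates in this package are 1-based
#' `c(x, y, z)` triples in the array's native order.
#'
#' @param data 3D numeric array of SUV values; finite and non-negative.
#' @param spacing per-axis voxel size in mm (length 3, positive); default 1 mm.
#' @param origin physical offset in mm (length 3); default zeros.
#' @return An object of class `suv_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
suv_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(!is.finite(data)) || any(data < 0))
    stop("SUV values must be finite and non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Acquisition metadata for SUV conversion
#'
#' @param injected_activity injected tracer activity in Bq (> 0).
#' @param body_weight patient body weight in kg (> 0).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity, body_weight) {
  if (!is.numeric(injected_activity) || length(injected_activity) != 1L ||
      !is.finite(injected_activity) || injected_activity <= 0)
    stop("invalid metadata: `injected_activity` must be a positive number (Bq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("invalid metadata: `body_weight` must be a positive number (kg)")
  structure(list(injected_activity = injected_activity,
                 body_weight = body_weight),
            class = "acquisition_meta")
}

#' Volume-of-interest mask
#'
#' A binary voxel mask on the same grid as its parent volume. The `role`
#' label records which pipeline object the mask represents.
#'
#' @param data 3D logical (or 0/1) array.
#' @param role one of `"lesion"`, `"eroded_lesion"`, `"surface"`,
#'   `"necrotic_core"`.
#' @return An object of class `voi_mask` with fields `data` (logical array)
#'   and `role`.
#' @export
voi_mask <- function(data, role = c("lesion", "eroded_lesion", "surface",
                                    "necrotic_core")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be 0/1")
    data <- array(data == 1, dim(data))
  }
  if (!is.logical(data)) stop("mask must be logical or 0/1")
  structure(list(data = data, role = role), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask role=%s> %s voxels, n = %d\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a `voi_mask`.
#' @return integer voxel count.
#' @export
mask_n <- function(mask) sum(mask$data)

#' Convert an activity-concentration volume to SUV
#'
#' SUV = measured activity concentration (Bq/mL) / (injected activity (Bq) /
#' (body weight (kg) x 1000)). The denominator is the injected activity
#' diluted over the body mass expressed in grams, so a voxel whose
#' concentration equals the whole-body average has SUV 1.
#'
#' @param activity 3D numeric array of activity concentration in Bq/mL
#'   (finite, non-negative).
#' @param meta an [acquisition_meta()].
#' @param spacing,origin passed to [suv_volume()].
#' @return An [suv_volume()] of the same shape.
#' @export
suv_from_activity <- function(activity, meta, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (!inherits(meta, "acquisition_meta"))
    stop("invalid metadata: `meta` must be an acquisition_meta object")
  if (!is.array(activity) || length(dim(activity)) != 3L)
    stop("`activity` must be a 3D array")
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity values must be finite and non-negative")
  suv <- activity / (meta$injected_activity / (meta$body_weight * 1000))
  suv_volume(suv, spacing = spacing, origin = origin)
}

#' Maximum SUV within a volume of interest
#'
#' @param vol an [suv_volume()].
#' @param voi a [voi_mask()] on the same grid.
#' @return the maximum SUV over the masked voxels (SUVmax).
#' @export
suv_max <- function(vol, voi) {
  stopifnot(inherits(vol, "suv_volume"), inherits(voi, "voi_mask"))
  if (!identical(dim(vol$data), dim(voi$data)))
    stop("volume and VOI shapes differ")
  if (!any(voi$data)) stop("empty region: VOI contains no voxels")
  max(vol$data[voi$data])
}

#' Read and write volumes and masks as NIfTI-1
#'
#' Volumes are stored as scalar 3D NIfTI-1 images; masks are written as
#' unsigned 8-bit 0/1 images. Voxel spacing is carried in the NIfTI pixdim.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns an [suv_volume()]; `read_mask` a
#'   [voi_mask()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("I/O error: expected a 3D volume, got ", length(dm), " dimensions")
  a <- array(as.vector(as.array(img)), dm)   # plain array, no NIfTI attributes
  suv_volume(a, spacing = RNifti::pixdim(img))
}

#' @param vol an [suv_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param mask a [voi_mask()].
#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param role role label for the mask being read.
#' @rdname read_volume
#' @export
read_mask <- function(path, role = "lesion") {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("I/O error: expected a 3D mask, got ", length(dm), " dimensions")
  voi_mask(array(as.vector(as.array(img)) != 0, dm), role = role)
}
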