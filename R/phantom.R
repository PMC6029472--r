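#' Specification of a digital SUV phantom
#'
#' Describes an ellipsoidal uterine-mass phantom on a uniform background,
#' with one of six uptake phenotypes:
#' \describe{
#'   \item{hollow_ball}{avid rim around an abruptly photopenic (possibly
#'     eccentric) necrotic core — the malignant phenotype of coagulative
#'     tumor necrosis.}
#'   \item{hyaline}{same geometry but a gradual sigmoid transition of width
#'     `transition_width` between core and rim — benign hyaline
#'     degeneration.}
#'   \item{heterogeneous}{moderate uptake with several Gaussian hot blobs.}
#'   \item{focal}{moderate uptake with a single small hot blob.}
#'   \item{diffuse_low, diffuse_high}{uniform uptake at a lower or higher
#'     level.}
#' }
#' The pristine pattern is perturbed with Gaussian noise whose standard
#' deviation is proportional to the local mean and then blurred with a
#' Gaussian point-spread function (default FWHM 4.80 mm, a typical clinical
#' PET axial resolution); blurring the noise together with the pattern
#' yields the spatially correlated noise texture of reconstructed PET.
#'
#' @param pattern uptake phenotype, see above.
#' @param grid_shape voxel grid dimensions; default `c(64, 64, 64)`.
#' @param spacing voxel size in mm; default 4 mm isotropic.
#' @param tumor_radii ellipsoid semi-axes in mm (length 3 or scalar).
#' @param core_radii necrotic-core semi-axes in mm (hollow_ball/hyaline).
#' @param core_offset core center offset from tumor center, mm.
#' @param rim_suv SUV of viable tumor tissue (the uniform lesion level for
#'   the benign patterns).
#' @param core_suv SUV of the necrotic core (hollow_ball/hyaline).
#' @param background_suv SUV outside the tumor.
#' @param transition_width mm over which the core-to-rim transition occurs
#'   (0 = abrupt step; the hyaline default is 20 mm).
#' @param core_texture_frac amplitude of residual heterogeneous uptake
#'   inside the necrotic core, as a fraction of the rim-core contrast;
#'   default 0.25. Necrotic tissue on FDG PET is photopenic but not a
#'   uniform void (residual inflammatory uptake, hemorrhage, partial
#'   volume); set to 0 for a pristine uniform core.
#' @param noise_sigma_frac standard deviation of the raw (pre-blur) voxel
#'   noise as a fraction of the local mean; default 0.25. The PSF stage
#'   correlates and attenuates this to roughly a 4% voxel coefficient of
#'   variation in the final image, typical of reconstructed clinical FDG
#'   PET.
#' @param psf_fwhm Gaussian PSF full width at half maximum in mm; default
#'   4.80.
#' @param rng_seed integer seed; identical seeds give identical volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(pattern = c("hollow_ball", "hyaline", "heterogeneous",
                                     "focal", "diffuse_low", "diffuse_high"),
                         grid_shape = c(64, 64, 64), spacing = c(4, 4, 4),
                         tumor_radii = 50, core_radii = 25,
                         core_offset = c(0, 0, 0),
                         rim_suv = NULL, core_suv = 1, background_suv = 0.5,
                         transition_width = NULL, core_texture_frac = 0.25,
                         noise_sigma_frac = 0.25,
                         psf_fwhm = 4.80, rng_seed = 1L) {
  pattern <- match.arg(pattern)
  if (is.null(rim_suv))
    rim_suv <- switch(pattern, hollow_ball = 8, hyaline = 8,
                      heterogeneous = 3.5, focal = 3, diffuse_low = 3,
                      diffuse_high = 6)
  if (is.null(transition_width))
    transition_width <- if (pattern == "hyaline") 20 else 0
  tumor_radii <- rep(as.numeric(tumor_radii), length.out = 3)
  core_radii <- rep(as.numeric(core_radii), length.out = 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  spec <- structure(list(
    pattern = pattern, grid_shape = as.integer(grid_shape), spacing = spacing,
    tumor_radii = tumor_radii, core_radii = core_radii,
    core_offset = as.numeric(core_offset), rim_suv = rim_suv,
    core_suv = core_suv, background_suv = background_suv,
    transition_width = transition_width,
    core_texture_frac = core_texture_frac,
    noise_sigma_frac = noise_sigma_frac, psf_fwhm = psf_fwhm,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  if (any(c(spec$rim_suv, spec$core_suv, spec$background_suv) < 0))
    stop("invalid spec: SUV parameters must be non-negative")
  if (pattern %in% c("hollow_ball", "hyaline") &&
      any(abs(spec$core_offset) + spec$core_radii > spec$tumor_radii))
    stop("invalid spec: necrotic core extends outside the tumor")
  spec
}

# Separable Gaussian blur; sigma per axis in voxels. Kernel truncated at
# 4 sigma and normalized, zero padding at the grid border.
gaussian_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq_along(k)) {
      off <- c(0L, 0L, 0L); off[ax] <- j - r - 1L
      acc <- acc + k[j] * shift3d(a, off, fill = 0)
    }
    a <- acc
  }
  a
}

#' Generate a phantom volume with ground truth
#'
#' Builds the pristine pattern, records the geometric ground-truth masks,
#' then applies the PSF blur and the intensity-proportional Gaussian noise
#' (clipped at zero). Masks reflect the pre-blur, pre-noise geometry.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: `volume` ([suv_volume()]),
#'   `tumor_mask` (role `"lesion"`), `core_mask` (role `"necrotic_core"`,
#'   empty for patterns without a necrotic core), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$rng_seed)
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  # physical coordinates (mm) of each voxel relative to the grid center
  xs <- (seq_len(d[1]) - ctr[1]) * spec$spacing[1]
  ys <- (seq_len(d[2]) - ctr[2]) * spec$spacing[2]
  zs <- (seq_len(d[3]) - ctr[3]) * spec$spacing[3]
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  tumor <- (X / spec$tumor_radii[1])^2 + (Y / spec$tumor_radii[2])^2 +
    (Z / spec$tumor_radii[3])^2 <= 1
  img <- array(spec$background_suv, d)
  core <- array(FALSE, d)

  if (spec$pattern %in% c("hollow_ball", "hyaline")) {
    # normalized ellipsoidal distance from the core surface, in mm
    u <- sqrt(((X - spec$core_offset[1]) / spec$core_radii[1])^2 +
              ((Y - spec$core_offset[2]) / spec$core_radii[2])^2 +
              ((Z - spec$core_offset[3]) / spec$core_radii[3])^2)
    core <- tumor & (u <= 1)
    dmm <- (u - 1) * mean(spec$core_radii)
    w <- spec$transition_width
    if (w <= 0) {
      val <- ifelse(u <= 1, spec$core_suv, spec$rim_suv)
    } else {
      # logistic whose 12%-88% rise spans the transition width
      val <- spec$core_suv +
        (spec$rim_suv - spec$core_suv) / (1 + exp(-dmm / (w / 4)))
    }
    if (spec$core_texture_frac > 0) {
      # Residual heterogeneous uptake: necrotic tissue is photopenic but not
      # a uniform void, and viable tumor tissue is itself heterogeneous.
      # Three bumps seeded in the core, three anywhere in the tumor.
      contrast <- spec$rim_suv - spec$core_suv
      for (b in 1:6) {
        if (b <= 3) {
          bc <- spec$core_offset + runif(3, -0.4, 0.4) * spec$core_radii
          bs <- runif(1, 0.25, 0.5) * mean(spec$core_radii)
        } else {
          bc <- runif(3, -0.6, 0.6) * spec$tumor_radii
          bs <- runif(1, 0.15, 0.3) * mean(spec$tumor_radii)
        }
        amp <- runif(1, 0.5, 1) * spec$core_texture_frac * contrast
        bump <- amp * exp(-((X - bc[1])^2 + (Y - bc[2])^2 + (Z - bc[3])^2) /
                            (2 * bs^2))
        val <- val + bump
      }
    }
    img[tumor] <- val[tumor]
  } else if (spec$pattern %in% c("diffuse_low", "diffuse_high")) {
    img[tumor] <- spec$rim_suv
  } else {
    n_blob <- if (spec$pattern == "focal") 1L else 3L + rpois(1, 1)
    img[tumor] <- spec$rim_suv
    for (b in seq_len(n_blob)) {
      bc <- runif(3, -0.5, 0.5) * spec$tumor_radii
      bs <- runif(1, 0.15, 0.3) * mean(spec$tumor_radii)
      amp <- if (spec$pattern == "focal") runif(1, 1.5, 2.5) else runif(1, 0.8, 2)
      bump <- amp * exp(-((X - bc[1])^2 + (Y - bc[2])^2 + (Z - bc[3])^2) /
                          (2 * bs^2))
      img[tumor] <- img[tumor] + bump[tumor]
    }
  }

  # Noise is applied to the pristine pattern and then blurred together with
  # it: reconstructed-PET noise is spatially correlated at about the
  # reconstruction resolution, and the correlation is what keeps redigitized
  # images free of the exact-zero gradient plateaus that a quantized,
  # voxelwise-independent noise field would create.
  if (spec$noise_sigma_frac > 0)
    img <- pmax(img + rnorm(length(img)) * (spec$noise_sigma_frac * img), 0)
  if (spec$psf_fwhm > 0) {
    sigma_vox <- (spec$psf_fwhm / 2.355) / spec$spacing
    img <- gaussian_blur3(img, sigma_vox)
  }
  img <- pmax(img, 0)

  structure(list(volume = suv_volume(img, spacing = spec$spacing),
                 tumor_mask = voi_mask(tumor, role = "lesion"),
                 core_mask = voi_mask(core, role = "necrotic_core"),
                 spec = spec),
            class = "phantom_truth")
}

#' Generate a reproducible synthetic cohort
#'
#' Expands per-pattern counts into jittered [phantom_spec()]s and generates
#' each phantom. Malignant phantoms are hollow-ball lesions with an
#' eccentric core; benign phantoms use the four benign phenotypes. Lesion
#' diameters are drawn to span roughly 5-17 cm, matching the clinical size
#' range of rapidly growing uterine masses.
#'
#' @param counts named integer vector of phantoms per pattern; the default
#'   mirrors a 21-patient cohort: 8 hollow_ball, 4 heterogeneous, 4 focal,
#'   4 diffuse_low, 1 diffuse_high.
#' @param seed master seed; per-phantom seeds and geometry jitter derive
#'   from it deterministically.
#' @param grid_shape,spacing forwarded to [phantom_spec()].
#' @return list of `phantom_truth` objects, one per phantom, each carrying a
#'   `pattern` element in its spec.
#' @export
phantom_cohort <- function(counts = c(hollow_ball = 8, heterogeneous = 4,
                                      focal = 4, diffuse_low = 4,
                                      diffuse_high = 1),
                           seed = 1L, grid_shape = c(64, 64, 64),
                           spacing = c(4, 4, 4)) {
  patterns <- rep(names(counts), counts)
  if (!length(patterns)) return(list())
  set.seed(as.integer(seed))
  specs <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[i]
    radii <- runif(3, 30, 70)   # semi-axes mm -> diameters 6-14 cm
    if (p %in% c("hollow_ball", "hyaline")) {
      core_frac <- runif(1, 0.35, 0.55)
      core_radii <- radii * core_frac
      # eccentric but fully contained
      max_off <- radii - core_radii
      offset <- runif(3, -0.6, 0.6) * max_off
    } else {
      core_radii <- radii * 0.4
      offset <- c(0, 0, 0)
    }
    sub_seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483629L
    specs[[i]] <- phantom_spec(pattern = p, grid_shape = grid_shape,
                               spacing = spacing, tumor_radii = radii,
                               core_radii = core_radii, core_offset = offset,
                               rng_seed = sub_seed)
  }
  lapply(specs, generate_phantom)
}
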