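---
title: "The metabolic tumor/necrosis ratio: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metabolic tumor/necrosis ratio: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnrpet)
```

## The measurement problem

Uterine leiomyosarcoma (LMS) and STUMP are defined histologically in part
by *coagulative tumor cell necrosis*: dead tumor with an abrupt boundary
against viable tissue. On FDG PET this appears as a photopenic core with a
sharp edge inside an avid rim — the "hollow ball" sign. Benign leiomyomas
degenerate *hyalinely*: uptake declines gradually toward the center with no
abrupt edge. The metabolic tumor/necrosis ratio turns this qualitative
visual sign into a number:

$$\mathrm{ratio} \;=\;
  \frac{\text{surface tumor metabolism}}{\text{necrotic core metabolism}},$$

where both metabolisms are mean *redigitized* intensities (integer bins
0–15) over automatically segmented VOIs. A homogeneous lesion gives a
ratio near 1; a photopenic core drives the denominator down and the ratio
up. In the bundled clinical table the benign ratios span 0.896–1.069 and
the malignant ones 1.421–5.533, with no overlap.

## The pipeline and its assumptions

1. **Lesion mask M1.** The 26-connected component of voxels with
   SUV ≥ 2.5 containing (or nearest to) the operator's click, with
   *enclosed cavities filled*. Filling is essential rather than cosmetic:
   a necrotic core sits below the 2.5 threshold, and without filling it
   would be excluded from the VOI entirely — the lesion would be a hollow
   shell and the core unmeasurable. A cavity is any background region not
   6-connected to the grid border. The click may be inexact; a
   sub-threshold click snaps to the nearest supra-threshold voxel
   (Euclidean, voxel units), refusing if that lies farther than
   `snap_radius` (default 20 voxels).
2. **Redigitization.** Bins `round_half_up(15 (v - min)/(max - min))`,
   the only linear map sending the in-lesion minimum to 0 and maximum to
   15 with 16 equally spaced levels. Bins are invariant under positive
   affine rescaling of the input, so the ratio does not depend on
   calibration offsets that leave contrast intact. A constant lesion is a
   degenerate-lesion error.
3. **Intensity-weighted gradient (IWG).** Central differences of the bin
   image in voxel units (the algorithm is deliberately agnostic to
   physical spacing; spacing matters only to the phantom PSF), Euclidean
   magnitude, multiplied by the *original* SUV image. The SUV weight is
   what makes the necrotic core — homogeneous *and* photopenic — the
   global minimum rather than any flat region of avid rim. Outside-M1
   voxels enter the difference stencil as 0, which creates a high-gradient
   rind at the lesion edge; the seed search below is therefore restricted
   away from the boundary.
4. **Smooth, then erode.** A 3×3×3 mean filter (zero-padded borders)
   followed by one grayscale erosion (3×3×3 minimum; voxels outside the
   grid do not constrain the minimum). Erosion of the *image* was chosen
   over erosion of the *mask* as the primary reading; in addition the seed
   search mask is M1 binary-eroded once, so that edge-rind voxels can
   never seed the core. Both protections are deliberate and independent.
5. **Seed and region growing.** The seed is the minimum of the processed
   IWG within the eroded lesion mask (ties: smallest linear array index;
   if the lesion is too thin to erode, the full mask is used with a
   warning). The necrotic core VOI is the 6-connected component of
   voxels with IWG ≤ 3 × seed value, grown inside full M1 (the core may
   legitimately reach within one voxel of the boundary). 6-connectivity
   keeps the core conservative; the lesion component itself uses
   26-connectivity (visual contiguity). Growth is set-defined, hence
   independent of traversal order — the tests confirm equality with a
   shuffled depth-first oracle.
6. **Surface shell.** k = max(1, round(n^(1/3) × 0.1)) binary erosions
   (halves round away from zero) of M1 give M2; the shell is M1 \ M2.
   The cube root ties shell thickness to lesion diameter; the clamp to
   k ≥ 1 guarantees a nonempty definition, and if erosion extinguishes the
   mask the shell falls back to M1 with a warning. Core and shell may
   overlap (eccentric cores); the overlap fraction is reported as a
   diagnostic.
7. **Ratio.** Arithmetic means of integer bins at full float precision;
   reports print 3 decimals to match the precision of the bundled table.
   A core metabolism of exactly 0 raises an explicit undefined-ratio error
   carrying all intermediates — never a silent infinity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `suv_threshold` | 2.5 | lesion boundary SUV (dimensionless) |
| `snap_radius` | 20 voxels | max click-to-lesion snap distance |
| ratio cutoff | 1.25 | malignancy call on the ratio |
| SUVmax cutoff | 4.5 | malignancy call on SUVmax |

The ratio cutoff 1.25 is a midpoint-region value between the largest
benign (1.069) and smallest malignant (1.421) ratio in the bundled table;
any value in that open interval classifies the 14 evaluable patients
identically. The SUVmax operating point 4.5 is treated as a *given*
parameter: re-deriving an "optimal" cutoff by the Youden index on the
printed per-patient values actually yields a higher J at a lower cutoff
(`roc_curve()` reports the full curve), and the original selection
criterion is not recoverable, so the published operating point is applied
as-is rather than re-derived.

Classification uses a strict `>` at the cutoff. No score in the bundled
table equals a cutoff, so this choice is unambiguous for reproduction; it
is documented for general use.

## The phantom generator

`generate_phantom()` emulates the uptake phenotypes the method must
distinguish, with ground truth:

* `hollow_ball` — ellipsoidal tumor (default semi-axis 50 mm), avid rim
  (SUV 8) around an abruptly photopenic, possibly eccentric core
  (SUV 1, default semi-axis 25 mm) — the malignant phenotype;
* `hyaline` — identical geometry with a sigmoid transition (default width
  20 mm) — benign degeneration. As `transition_width` grows the
  hollow-ball pattern converges to it, and the computed ratio falls
  monotonically toward the benign regime (tested);
* `heterogeneous`, `focal`, `diffuse_low`, `diffuse_high` — the four
  benign patterns: moderate uptake with Gaussian hot blobs, a single
  focal blob, or uniform uptake at SUV 3 or 6.

Each pattern sits on a 0.5-SUV background in a 64³ grid of 4 mm isotropic
voxels (PET voxel size is not standardized; 4 mm is typical and
configurable), is blurred with a Gaussian PSF of FWHM 4.80 mm (a typical
clinical axial resolution at the gantry center), and carries Gaussian
voxel noise with σ proportional to the local mean.

Two generator choices deserve explanation because they decide whether the
synthetic cohort behaves like clinical data at all:

* **Noise is applied before the PSF.** Reconstructed-PET noise is
  spatially correlated at roughly the reconstruction resolution; blurring
  the noise together with the pattern produces exactly that texture. The
  alternative — independent voxel noise added after the blur — leaves the
  16-bin quantized core as a mathematically flat plateau: the IWG is then
  *exactly* zero there, the seed threshold 3 × 0 = 0 degenerates, and
  every abrupt-core phantom lands in the undefined-ratio error path, a
  situation real images never produce. The default pre-blur fraction is
  0.25; the PSF attenuates independent voxel noise by roughly ×0.16, so
  the reconstructed image carries a ≈ 4% voxel coefficient of variation,
  clinically typical.
* **Necrotic cores have residual texture.** A perfectly uniform SUV-1
  void is not what necrosis looks like on PET (residual inflammatory
  uptake, hemorrhage, partial-volume mixing), and the clinical ratios
  imply core metabolisms of roughly bins 2–8, never 0.
  `core_texture_frac` (default 0.25 of the rim–core contrast) adds a few
  smooth Gaussian bumps inside the core, and — since viable tumor tissue
  is itself heterogeneous — similar bumps across the tumor. Setting it to
  0 recovers the pristine geometric phantom used by the exact-geometry
  unit tests.

`phantom_cohort()` mirrors the clinical cohort composition: 8 hollow-ball
and 13 benign phantoms (4 heterogeneous, 4 focal, 4 diffuse-low,
1 diffuse-high), with per-phantom jittered geometry (semi-axes 30–70 mm,
core fraction 0.35–0.55, eccentric offsets) derived deterministically from
one master seed. Two labels differ numerically from the clinical table:
the patients read as "diffuse low" had SUVmax 2.0–2.5, *below* the 2.5
segmentation threshold — a lesion the pipeline, by design, refuses to
segment (and the phantom reproduces that refusal when asked for SUV 2.0).
The cohort's diffuse-low phantoms therefore sit at SUV 3, keeping the
label as a relative descriptor of a segmentable lesion.

What the phantoms do *not* emulate: sinogram-level physics (attenuation,
scatter, Poisson counting), adjacent FDG-avid organs (bladder), motion,
and real histological texture. Passing the synthetic-cohort tests
therefore shows that the pipeline orders abrupt-core against gradual and
homogeneous lesions correctly under realistic blur and noise — not that
the clinical ratio values themselves are recovered; the raw clinical
images are unrecoverable, and the absolute bundled ratios enter only
through the cohort-statistics module.

Under these defaults the synthetic cohort separates cleanly: across eight
master seeds the malignant ratios stayed above 1.4 (minima 1.6–4.6) and
every benign ratio stayed near 1 (maxima ≤ 1.01, minima mostly ≥ 0.87
with occasional excursions to ≈ 0.81, caused by the surface shell
catching the cold blurred lesion edge while the core region lands on a
warmer interior pocket). The clinical benign minimum, 0.896, shows the
same sub-unity tendency.

## Numerical conventions and degenerate inputs

* Voxel coordinates are 1-based `c(x, y, z)` in the array's native order
  (the NIfTI fastest-first convention as read by `RNifti`); all reported
  seeds use it.
* Halves round *up* in redigitization and *away from zero* in the shell
  thickness k (identical for the positive arguments that occur); R's
  banker's rounding is never used.
* Ties in seed selection resolve to the smallest linear array index,
  which is the lexicographically smallest coordinate scanning z, then y,
  then x — deterministic and platform-independent.
* Border handling: the mean filter zero-pads; grayscale erosion treats
  out-of-grid as +∞ (no constraint); binary erosion treats out-of-grid as
  background, so border voxels always erode.
* Degenerate inputs have explicit error paths: no supra-threshold voxel
  (no-lesion), click too far from lesion (seed-mismatch), constant lesion
  (degenerate-lesion), empty VOIs (empty-region), zero core metabolism
  (undefined-ratio, with intermediates attached).

## Cohort statistics

`mann_whitney()` uses mid-ranks and computes the *exact* permutation
two-tailed p by full enumeration whenever the group assignment count is at
most 5×10⁵ (the 8-vs-13 cohort comparison enumerates all 203 490
assignments, so the exact p is available even with the tied SUVmax
values), alongside the tie-corrected normal approximation; both are
reported because the original software's convention for this sample size
is not recoverable (exact 0.0024, asymptotic 0.0037 for SUVmax — both
round to the published neighborhood of 0.003). `mcnemar_exact()` is the
closed-form binomial tail; 5-vs-0 discordant pairs give 0.0625, printed
as 0.063. Pearson correlation delegates to `cor.test`. Percentages round
half-up to integers, with the exact fractions always reported alongside.

One documented inconsistency: the published cohort-level benign size range
starts at 4.5 cm, but the per-patient minimum in the same publication's
table is 5.0 cm. The package stores the per-patient table verbatim and
computes summaries from it; the discrepancy is surfaced here rather than
silently reconciled.

## Problem sizes

The test suite and the acceptance script run the full synthetic cohort at
the default 64³ grid (a 25.6 cm field of view at 4 mm voxels, enough for
the largest 17 cm lesions), with property tests on 48³ phantoms and
oracle comparisons on ≤ 8³ random instances; the complete suite runs in
about a minute on one CPU.

## Known limitations

* The pipeline expects one lesion per call; multi-lesion batch detection
  and physician-drawn contour import are out of scope. A configurable
  bounding box is available to exclude adjacent avid structures, but no
  clinical protocol for it is encoded.
* The ratio is undefined when the necrotic core VOI averages exactly
  bin 0 — possible for synthetic images with mathematically flat cores,
  raised as an explicit error.
* Diagnostic statistics are transcription-faithful to a single 21-patient
  retrospective cohort; they are reproduction tooling, not new evidence.
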