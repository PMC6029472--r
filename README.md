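# tnrpet

Quantifying coagulative tumor necrosis on FDG PET to tell uterine
leiomyosarcoma (LMS) and smooth muscle tumors of uncertain malignant
potential (STUMP) apart from benign leiomyomas.

Rapidly growing uterine masses are usually benign fibroids, but a
leiomyosarcoma mistaken for one and morcellated at surgery is a
catastrophe. SUVmax alone does not discriminate well: malignant and benign
uterine smooth-muscle tumors overlap broadly in peak FDG uptake. What does
discriminate is the *spatial pattern* of uptake: LMS/STUMP contain
coagulative tumor necrosis — a photopenic core with an abrupt edge inside a
metabolically avid rim (the "hollow ball" sign) — whereas benign
degeneration is gradual and hyaline, with no abrupt core.

`tnrpet` implements a quantitative surrogate for this sign, the **metabolic
tumor/necrosis ratio**, for nuclear-medicine researchers working with 3D
PET volumes (NIfTI-1, SUV or Bq/mL):

```
ratio = surface tumor metabolism / necrotic core metabolism
```

computed fully automatically from an operator's approximate click on the
lesion:

1. **Lesion VOI (M1)** — 26-connected component at SUV ≥ 2.5, enclosed
   photopenic cavities filled.
2. **Redigitization** — in-lesion intensities linearly mapped to 16 integer
   bins, min → 0, max → 15.
3. **Intensity-weighted gradient** — central-difference gradient magnitude
   of the binned image × original SUV; low where tissue is both homogeneous
   and photopenic.
4. **Smoothing + erosion** — 3×3×3 mean filter, then one grayscale erosion.
5. **Seed + region growing** — the gradient minimum seeds a 6-connected
   region grown at threshold 3 × seed value: the *necrotic core VOI*.
6. **Surface shell** — M1 eroded k times (k = max(1, round(n^⅓ × 0.1)),
   n = lesion voxels) gives M2; the shell is M1 \ M2.
7. **Ratio** — mean bin value over the shell divided by mean bin value over
   the core. ≈ 1 for homogeneous (benign-type) lesions, elevated when a
   photopenic core is present.

The package also ships a seeded digital phantom generator (malignant
hollow-ball and four benign uptake phenotypes, Gaussian PSF of FWHM
4.80 mm, correlated voxel noise) with ground-truth masks, and the bundled
21-patient cohort table with every diagnostic statistic it supports
(confusion matrices, ROC/Youden, exact Mann–Whitney, Pearson, exact
McNemar).

## Worked example

```r
library(tnrpet)

# malignant-type phantom: avid rim, eccentric photopenic core
ph <- generate_phantom(phantom_spec("hollow_ball",
                                    core_offset = c(10, -6, 0),
                                    rng_seed = 42))
res <- compute_ratio(ph$volume, c(32, 32, 44))  # click on the rim
print(res)
#> Metabolic tumor/necrosis ratio
#>   ratio                 5.378
#>   surface metabolism    8.372 (mean bin, 0-15)
#>   core metabolism       1.557 (mean bin, 0-15)
#>   SUVmax                12.48
#>   lesion voxels n       8314  (shell thickness k = 2)
#>   seed voxel (x,y,z)    36,27,32
#>   core voxels           652 (overlap with shell 0.0%)
```

The ratio 5.378 sits far above the benign regime: the rim averages bin 8.4
while the necrotic core averages 1.6. The same call on a benign
heterogeneous phantom (`phantom_spec("heterogeneous", rng_seed = 42)`)
prints `ratio 0.942` — surface (4.18) and core (4.44) metabolism nearly
equal, as expected when no abrupt photopenic core exists.

Cohort statistics from the bundled patient table:

```r
rec <- load_cohort()
cm  <- confusion_at_cutoff(rec, "suv_max", 4.5)
diagnostic_metrics(cm)$percent
#> accuracy sensitivity specificity  ppv  npv
#>       76          75          77   67   83
```

A thin command-line front end is installed with the package
(`system.file("scripts", "tnr", package = "tnrpet")`) with subcommands
`compute`, `phantom`, `cohort`, and `reproduce`.

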