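# fetradiomics

Radiomics of visually FET-negative gliomas from dynamic PET, in R.

About a third of low-grade gliomas show no visually increased uptake of
the amino-acid tracer O-(2-[18F]fluoroethyl)-L-tyrosine (FET) — they are
either *isometabolic* (indistinguishable from healthy background in
static images) or *photopenic* (uptake below background). This package
implements, end to end, the quantitative analysis asking whether such
tumors are nevertheless separable from healthy tissue:

* **Parametric maps** from 4D dynamic PET (16 frames, 0–40 min p.i.):
  early TBR₅₋₁₅ and standard TBR₂₀₋₄₀ tumor-to-background-ratio images
  (summation images normalized by the mean of a crescent-shaped
  contralateral background VOI) and voxel-wise time-to-peak (TTP) maps —
  the mid-time in minutes of the first frame attaining each voxel's
  time-activity-curve maximum. Ascending kinetics (TTP > 30 min p.i.)
  are the dynamic signature of FET-negative tumor tissue.
* **93 radiomic features** per VOI and image kind — 18 first-order plus
  75 texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5),
  IBSI-style definitions, fixed-bin-count discretization, 13-direction
  averaging — extracted from the tumor VOI and from the same VOI
  mirrored into the contralateral hemisphere (ventricle excluded), so
  tumor and healthy tissue are compared at identical shape.
* **Paired screening**: per-feature two-sided Wilcoxon signed-rank tests
  of tumor vs. mirrored background (exact null for n ≤ 25 pairs, valid
  under ties), with a significance census per image kind and phenotype
  subgroup.
* **Classification**: nested cross-validated logistic regression
  (balanced class weights, L2 penalty, inner-CV tuning of the inverse
  regularization strength C, repeated stratified 5-fold outer loop),
  reporting mean ± sd ROC AUC per feature set and per single feature.
* **Synthetic cohort generator**: a seeded digital brain phantom with
  early-peaking background, ascending isometabolic and reduced
  photopenic tumor kinetics plus count-statistics Gaussian frame noise,
  so the full pipeline runs and is tested without any patient data.

## Worked example

```r
library(fetradiomics)

spec <- phantom_spec(grid_shape = c(36, 36, 26), tumor_center = c(28, 17, 13),
                     ventricle_center = c(16, 21, 13),
                     ventricle_radii_mm = c(8, 16, 12), noise_scale = 1)
pt <- simulate_patient(spec, default_tissue_params("isometabolic"), seed = 42)
pt
#> synthetic_patient (seed 42): tumor phenotype isometabolic
#> dynamic_image: 36x36x26 voxels (3 mm), 16 frames, 0-39.67 min p.i.
#> voi_set on 36x36x26 grid: tumor 515, mirrored 515, crescent 2808, ventricle 239 voxels

maps <- parametric_maps(pt$dynamic_image, pt$voi_set$crescent_mask)
tum <- pt$voi_set$tumor_mask; mir <- pt$voi_set$mirrored_mask
mean(maps$TBR_20_40$voxels[tum])  # 0.997 -- visually FET-negative
mean(maps$TBR_20_40$voxels[mir])  # 1.000
mean(maps$TTP$voxels[tum])        # 34.6 min -- ascending kinetics
mean(maps$TTP$voxels[mir])        # 3.5 min  -- early perfusion peak

fv <- extract_all(maps$TTP, tum)
round(fv[c("firstorder_Mean", "glcm_Idmn",
           "glrlm_HighGrayLevelRunEmphasis")], 3)
#>                firstorder_Mean                      glcm_Idmn
#>                         34.633                          0.998
#> glrlm_HighGrayLevelRunEmphasis
#>                       1014.659
```

The tumor is invisible in the late static image (TBR ≈ 1.0) but
kinetically obvious: its mean TTP sits 31 minutes later than the
mirrored healthy tissue, and TTP-derived texture features (high Idmn
homogeneity, high gray-level run emphasis) carry the contrast. At cohort
level, `significance_census()` tabulates how many of the 93 features
differ (p < 0.05, paired Wilcoxon) per image kind and subgroup, and
`nested_cv_auc()` / `univariate_auc()` quantify tumor-vs-background
discrimination. `run_full_pipeline()` executes everything from one
seeded `run_config()` and writes CSV/JSON artifacts stamped with the
config hash; `inst/cli/fetradiomics.R` exposes the stages as shell
subcommands (`simulate`, `maps`, `extract`, `featuremap`, `run-all`).

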