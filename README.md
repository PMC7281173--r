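# marrowrad

An [18F]FDG-PET radiomics pipeline for predicting bone-marrow involvement
in mantle cell lymphoma from pelvic bone uptake, for imaging researchers
who want every stage of such an analysis — segmentation, texture features,
scanner harmonization, dimensionality reduction, repeated-split
classification — as tested, reproducible code rather than a point-and-click
workflow.

Bone marrow biopsy is the reference standard for staging marrow involvement,
but it is invasive and samples one site. The pipeline quantifies the uptake
*pattern* of the pelvic marrow instead:

* **MTV segmentation** — the metabolic tumor volume is every search-region
  voxel with SUV ≥ 0.41 · SUVmax (ties included, one global region, no
  component filtering).
* **Radiomic features** — SUVmax, SUVmean, SUVpeak (1 cm³ sphere) plus 16
  Haralick features of the 3D gray-level co-occurrence matrix
  (e.g. entropy −ΣΣ P log P, contrast ΣΣ (i−j)² P(i,j), the informational
  measures of correlation), accumulated over the 13 unique distance-1
  directions after min-max discretization to 25 gray levels, then averaged.
* **ComBat harmonization** — parametric empirical-Bayes location/scale
  adjustment y\*ᵢg = σg·(zᵢg − γ\*ᵢg)/δ\*ᵢg + αg across the four scanner
  batches, with an explicit fit/apply split.
* **Radiomic signature** — correlation-matrix PCA of the 19 features,
  components retained by the Kaiser criterion (eigenvalue > 1).
* **Classification** — a tanh/softmax multi-layer perceptron (1 × 3 units by
  default) on three feature sets (SUVs; signature; signature + WBC, LDH),
  stratified 70/30 splits, five repetitions, reported as median (range) of
  train/test accuracy and Mann-Whitney AUC per endpoint
  (involvement, REL > 5/10 %, ABS > 5/10 %, Ki-67 ≥ 30 %).

A synthetic phantom module (Gaussian-random-field marrow texture, focal
lesions, four simulated scanners, covariates calibrated to the reference
cohort's reported moments) generates
complete cohorts, so the whole pipeline runs and is tested without any
patient data.

## Worked example

```r
library(marrowrad)
spec <- phantom_spec()                      # 64 x 64 x 32, 5.5 x 5.5 x 3.3 mm
mask <- generate_pelvis_mask(spec)
vol  <- generate_patient_volume(spec, involved = TRUE, rel_percent = 40,
                                effect = default_scanner_effects()$S2, seed = 7)
mtv  <- segment_mtv(vol, mask, fraction = 0.41)
mtv
#> MTV: 3075 voxels (306.96 mL), SUVmax 3.498, threshold 1.434 (41% SUVmax)
rec <- extract_features(vol, mtv$mtv_mask, patient_id = "P0001", scanner_id = "S2")
round(unlist(rec[c("suv_max", "suv_mean", "suv_peak",
                   "entropy", "contrast", "homogeneity", "correlation")]), 3)
#>     suv_max    suv_mean    suv_peak     entropy    contrast homogeneity correlation
#>       3.498       1.885       3.373       4.714       8.918       0.476       0.690
```

The record reads: the hottest MTV voxel has SUV 3.50 and its 1 cm³
neighbourhood averages 3.37; the marrow texture occupies many co-occurrence
cells (entropy 4.7 of a possible log 625 ≈ 6.4), with moderate local
gray-level jumps (contrast 8.9 on 25 levels) and substantial spatial
correlation (0.69) — a heterogeneous, spatially structured uptake pattern
typical of an involved marrow with REL 40 %.

The full chain, from simulated cohort to the median-(range) report grid:

```r
res <- run_pipeline(pipeline_config(n_patients = 97, seed = 1), out_dir = "results/")
print(res$report)
```

which writes `cohort.csv`, `features.csv`, `harmonized.csv`, `scores.csv`,
summary grids and a JSON manifest; reruns with the same config are
byte-identical. A thin CLI wrapper lives at `inst/cli/marrowrad.R`
(`Rscript marrowrad.R --config config.yaml --out results/`).

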