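---
title: "Methods: PET radiomics for bone-marrow involvement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics for bone-marrow involvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bone marrow biopsy of the iliac crest is the reference standard for
detecting marrow involvement in mantle cell lymphoma, but it is invasive and
prone to sampling error when infiltration is focal. `marrowrad` implements a
non-invasive alternative: quantify the [18F]FDG uptake pattern of the pelvic
bone marrow on PET and classify involvement from it. The pipeline has six
stages:

1. **Segmentation** of the pelvic metabolic tumor volume (MTV): all voxels of
   a pelvic-bone search region with SUV at or above 41% of the region's
   SUVmax.
2. **Feature extraction**: SUVmax, SUVmean, SUVpeak, and 16 Haralick texture
   features of the 3D gray-level co-occurrence matrix (GLCM) over the MTV.
3. **Harmonization**: parametric empirical-Bayes ComBat across the four
   scanner models of the cohort.
4. **Signature**: principal components of the 19 standardized features,
   retained by the Kaiser criterion (eigenvalue > 1).
5. **Classification**: a small tanh/softmax multi-layer perceptron on each
   of three feature sets (SUVs; signature; signature + WBC and LDH), with
   stratified 70/30 splits repeated five times.
6. **Reporting**: median (range) of training accuracy, test accuracy and
   Mann-Whitney AUC per endpoint and feature set.

Endpoints are involvement (biopsy positive vs negative), REL > 5% and
REL > 10% (REL: percentage of *cellular* marrow infiltrated; values at
exactly the threshold are negative), ABS > 5% and ABS > 10%
(ABS = cellularity × REL / 100, the fraction of the *whole* marrow space),
and — among involved patients only — Ki-67 ≥ 30%.

Because no patient data ship with the package, a synthetic phantom module
generates pelvic PET volumes and cohort tables with the class structure,
covariate distributions and scanner batch effects the analysis assumes, so
every stage is testable end to end.

## Segmentation

The MTV rule is a pure relative threshold: `MTV = { v in search :
SUV(v) >= 0.41 * max SUV over search }`. Design points:

* Ties at exactly the threshold are **included**, so the maximum voxel is
  always a member and the MTV is never empty.
* The pelvic bones are treated as **one region** with a single global
  SUVmax, not per-bone regions.
* **No connected-component filtering**: disconnected supra-threshold marrow
  uptake is biologically expected and retained.
* The search mask is assumed to already exclude bowel and muscle. In the
  original clinical workflow this exclusion was done by hand against CT;
  here it is a precondition on the input, which is a documented limitation.

An empty search region or an all-zero volume is an error, not an empty
result.

## Discretization and texture features

GLCM features require discrete gray levels. Two schemes are implemented:

* **fixed-bin-number** (default, `Ng = 25`):
  `level = min(Ng, floor(Ng * (x - min)/(max - min)) + 1)`. A constant
  region maps to a single level. Min-max binning makes the texture features
  invariant to per-patient intensity shifts and rescalings.
* **fixed-bin-width** (`level = floor((x - min)/w) + 1`): occupancy then
  grows with signal amplitude, which is the right tool when absolute
  SUV dispersion is itself the signal.

The default is 25 gray levels. A literal bin *width* of 25 SUV would place
every marrow voxel of an SUV-calibrated scan (values of order 1-3) into a
single bin and destroy all texture, so the bin-number reading is the only
self-consistent default for this data; both modes remain available and the
choice is recorded in the extraction metadata.

Co-occurrences are counted in 3D over the 13 unique Chebyshev-distance-1
directions, symmetrically (both orderings of each voxel pair), one matrix
per direction, normalized to sum 1. Features are computed per direction and
averaged unweighted over the non-empty directions; merging counts before
feature computation is available as a config alternative. No resampling to
isotropic voxels is performed — the 5.5 × 5.5 × 3.3 mm acquisition grid is
kept, and direction-wise features are anisotropic accordingly (their
13-direction average is still invariant under 90° axial rotations).

The 16 features are entropy, homogeneity, contrast, correlation, angular
second moment, difference entropy, difference variance, inverse difference
moment, sum average, sum entropy, sum variance, cluster prominence, cluster
shade, maximum probability, and the two informational measures of
correlation (IMC1, IMC2). Conventions:

* `0 log 0 = 0` throughout; natural log by default (base-2 switchable —
  affects the entropy family only).
* sum variance is centered on **sum average** (the standard erratum
  correction of the original formula, which centered it on sum entropy).
* Degeneracies: a single-gray-level matrix has correlation 1 (a constant
  region is perfectly predictable, and this is the limit of the formula as
  the two-level occupancy vanishes); IMC1 is 0 when `max(HX, HY) = 0`; IMC2
  clamps `1 - exp(·)` at 0 before the square root.
* SUVpeak uses a 1 cm³ sphere (radius 6.2 mm) of voxel centers around the
  max voxel, clipped to the image bounds.

Every feature is verified in the test suite against an independent
exhaustive-pair, double-loop oracle to 1e-10.

## ComBat harmonization

Scanner model is the batch. Per feature, the batch-size-weighted grand mean
and pooled residual scale standardize the data; per-batch location and scale
are estimated on the standardized values and shrunk toward normal /
inverse-gamma priors whose hyperparameters are moment-matched across
features, by the standard iterative parametric empirical-Bayes solver
(tolerance 1e-6, cap 100 iterations). The model object stores
`(alpha, sigma, gamma*, delta*)` so it can be serialized, audited, and
applied to new samples of known batch.

Choices worth knowing:

* All 19 features are harmonized by default (SUVs included), since both
  enter the downstream signature; texture-only harmonization is a switch.
* Laboratory values are **never** harmonized — they are not scanner-derived.
* No biological covariates are protected in the design (`--preserve`-style
  options default off).
* Shrinkage has a visible cost in an edge case: if *every* feature carries
  the *same* batch shift, the across-feature spread of batch effects — the
  empirical location-prior variance — is pure sampling noise, per-feature
  deviations are shrunk hard, and residual batch-mean gaps of ~0.2 SD can
  remain. This is a property of the standard algorithm (the `sva` reference
  implementation reproduces it to numerical identity, which the test suite
  checks), not of this implementation. With sign-varying batch effects the
  prior is honest and recovery is essentially exact.

## The radiomic signature

PCA is computed on the **correlation** matrix of the 19 features: they live
on wildly different scales (SUV units versus fourth-moment cluster
prominence), so covariance PCA would be dominated by the widest-scaled
feature. Components with eigenvalue > 1 are retained (Kaiser). The
decomposition is a closed-form symmetric eigendecomposition; no iteration is
involved, and determinacy up to sign is resolved by making each loading
column's largest-magnitude entry positive. A near-flat spectrum (all
eigenvalues ≈ 1, i.e. nearly independent features) makes the retained count
unstable and triggers a warning rather than a silent answer.

The signature is fit on the full cohort before splitting by default,
matching the original analysis order; a stricter train-only fit is available
(`pca_fit = "train"`) for leakage-sensitive reruns. Scores are exactly
centered on the fit data and mutually uncorrelated; reconstruction error
equals the discarded eigenvalue mass (both asserted in tests).

## Classification

The MLP is one hidden layer of three tanh units by default (the original
description gives only these minima; the auto-search of the original
software is not reproducible), a 2-unit softmax output, and cross-entropy
loss. Training is full-batch backpropagation gradient descent with a
backtracking line search: a step is accepted only if it lowers the
penalized loss, so the recorded loss trace is non-increasing by
construction, and a fit is a deterministic function of its seed. There is
no early stopping; a fixed epoch budget (500) with the
no-improvement/step-collapse guard keeps runs comparable across feature
sets.

Weight decay defaults to 0.02. In this pipeline's regime — roughly a
hundred training cases, at most eight inputs — even a three-unit network
fits the training split perfectly without a penalty, and its test
performance then varies erratically with the initialization; a ridge
penalty of this size restores stable generalization while leaving separable
problems separable.

Inputs are standardized with training-split statistics only, applied
unchanged to the test split. Five repetitions per endpoint × feature set
re-randomize the weight initialization by default, keeping one shared 70/30
stratified split (the reading that the repetitions address initialization
variance); re-randomizing the split as well (`vary = "both"`) is available
and is what the package's own end-to-end and permutation-null checks use,
since medians over independent splits estimate procedure-level performance
rather than one split's luck. The stratified split rounds the total
training size half-up and allocates it across classes by largest remainder,
so class proportions are preserved within one sample.

AUC is the Mann-Whitney concordance probability computed from midranks
(ties count 1/2), evaluated on the test split by default (an all-cases mode
exists for comparison).

## The phantom: what it emulates, and what it does not

The generator exists to make the pipeline testable, with the cohort
structure of the study population and the acquisition geometry
(64 × 64 × 32 voxels of 5.5 × 5.5 × 3.3 mm) as its fixed points.

**Cohort table.** Involvement prevalence 0.691. REL among involved is a
truncated normal on [0, 100] whose *mean* is calibrated exactly to 33.0 by
solving for the underlying normal location; the family cannot reach the
reported SD of 29.1 against the lower bound (a [0,100]-truncated normal
with mean 33 tops out near SD 25), so the realized SD is ~25 — the
moment-matched beta alternative (`rel_model = "beta"`) can match both
moments. Cellularity is truncnorm(68, 15): the study does not report it,
and 68% makes E[ABS] = E[cellularity]·E[REL]/100 ≈ 22.6 match the reported
ABS mean. WBC and LDH are class-conditional **lognormals** (reported WBC
dispersion, 10.5 ± 11.9, has cv > 1, which no 0-truncated normal can
represent; lab values are right-skewed anyway), with class means chosen so
the prevalence-weighted mixtures reproduce the reported overall moments
(10.5 and 232.3). Ki-67 is class-conditional truncated normal; a mean of
exactly 29.7 among involved and P(Ki-67 ≥ 30 | involved) = 0.493 are
jointly unreachable for a right-skewed distribution (median < mean), and
the study pins only the overall mixture mean (28.9) and the 0.493 fraction,
so the class parameters solve those two constraints: involved ≈ (31.95, 20),
uninvolved ≈ (22.1, 18).

**Volumes.** Marrow uptake is baseline 1.2 SUV plus a stationary Gaussian
random field (white noise convolved with a periodic Gaussian kernel via
FFT, renormalized to the target SD), over a deterministic two-sided
half-annulus "iliac wing" search mask. Involved patients receive a diffuse
mean shift (0.008 SUV per REL point), extra field amplitude (1% per REL
point), a REL-weighted variance-preserving mixture of the coarse
normal-marrow field (correlation length 18 mm by default) and a finer
infiltration field (10 mm), saturating at REL 40, and focal 11-mm spherical
lesions with Poisson count 0.05 × REL and +1.5 SUV. A per-patient,
class-independent baseline jitter (SD 0.1) models inter-patient metabolic
variability. Four scanners differ in Gaussian PSF (4-8 mm FWHM), gain
(0.9-1.1), offset (±0.05) and noise scale; blur, gain, offset and additive
noise are applied last and the result is clamped at 0. These scanner
magnitudes are strong enough that texture features show a significant
scanner main effect before harmonization (tested) and mild enough that
class signal survives it.

Not emulated: real pelvic anatomy, CT, attenuation and reconstruction
physics, respiratory motion, and the empirical joint distribution of real
marrow texture with disease. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that its qualitative behavior (texture
adds information beyond SUVs when texture is where the signal is) holds on
data with known ground truth — not that the published effect sizes transfer
to any clinical cohort.

**The texture-only study condition.** The package's end-to-end check asks
whether the signature beats SUVs when the classes differ in texture but not
in mean uptake. That condition is instantiated as: no mean shift, no
lesions, equal field amplitude (0.2 SUV), correlation-length contrast 30 mm
vs 8 mm with mixture saturation at REL 30, and baseline jitter 0.15. The
jitter matters: SUVmax is an extreme-value statistic and rises with the
effective number of independent texture patches, so without a nuisance on
the intensity scale even an "equal-mean" cohort leaks class information
into the SUV features, while min-max-binned texture features are invariant
to it by construction. Under this condition the measured ordering is
SUVs ≈ 0.75 < signature ≈ 0.87-0.95 ≤ signature+labs, reproducing the
qualitative ordering of the original study at desk scale.

## Problem sizes and numerical choices

The test suite and the acceptance script run on one CPU in a few minutes:
the end-to-end cohort is n = 200 (one 64 × 64 × 32 volume per patient),
ComBat recovery uses 20 simulated two-batch tables of 19 features × 200
samples, PCA recovery 20 factor-model draws at n = 500, and oracle
equivalence checks run on 4 × 4 × 3 volumes where exhaustive enumeration is
exact. All randomness derives from explicit integer seeds through a
Lehmer-style `derive_seed(master, index)` map, so any stage can be rerun in
isolation and cohorts, splits and weight initializations are all
individually reproducible. Volumes round-trip NIfTI-1 as float32; SUV
negativity is an I/O error rather than a clamp (clamping is the phantom's
job, at generation time).

## Known limitations

* The pelvis mask is a geometric stand-in, not anatomy; MTV volumes in mL
  are internally consistent but not clinically meaningful.
* The truncated-normal REL generator under-disperses by design limits (see
  above).
* ComBat's location shrinkage leaves small residual batch means when batch
  effects are identical across all features (see above).
* The published AUC magnitudes depend on 97 undistributed patient scans and
  are not reproducible from this package; only the in-text arithmetic on
  printed counts and the qualitative feature-set ordering are.
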