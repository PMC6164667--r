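---
title: "Rotation-invariant texture analysis of MRI ROIs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-invariant texture analysis of MRI ROIs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roitexture)
```

## The problem

Textural properties of brain tissue on T1-weighted MRI — how intensities
co-vary between neighbouring voxels — change with neurodegeneration before
gross atrophy is obvious. `roitexture` implements a compact radiomics
pipeline for testing whether such texture differences discriminate clinical
groups: place small circular (single-slice) or spherical ROIs at anatomical
seed points (the motivating application is the hippocampus, with three
concentric ROIs of radius 3, 5 and 8 voxels per side), extract a fixed panel
of 25 statistical texture features per ROI, and screen every feature for
group differences with standard tests under multiple-comparison control.

The package deliberately works in each image's native voxel grid. For small,
equal-sized geometric ROIs, spatial normalization adds little and can
distort the very texture being measured, so no registration or resampling is
performed anywhere.

## Per-ROI pipeline

Each ROI goes through three stages.

**Outlier rejection.** Intensities under the mask are summarized by their
mean $\mu$ and population standard deviation $\sigma$; voxels outside
$[\mu - 3\sigma,\ \mu + 3\sigma]$ are *rejected* — removed from the ROI
grid, not clipped to the boundary. A rejected voxel becomes a hole: it
contributes to no histogram, no co-occurrence pair and no run. The
population form of $\sigma$ (divide by $n$) is used; at ROI sizes of tens to
thousands of voxels the difference from the sample form is immaterial, but
fixing it makes results bit-reproducible. The multiplier 3 is configurable
(`sigma_multiplier`). By Chebyshev's inequality the rejected fraction never
exceeds $1/9$ for any intensity distribution; for roughly Gaussian ROIs it
is near $2\Phi(-3) \approx 0.27\%$.

**Quantization.** Surviving intensities are binned uniformly onto
$N_g = 64$ gray levels (6 bits):
$\mathrm{level}(x) = \min\!\big(\lfloor (x - x_{\min}) N_g / (x_{\max} -
x_{\min}) \rfloor + 1,\ N_g\big)$, with $x_{\min}, x_{\max}$ taken over the
ROI's valid voxels; a constant ROI maps to level 1. Because only the
position of $x$ within $[x_{\min}, x_{\max}]$ matters, every downstream
feature is invariant to positive affine intensity rescaling — scanner gain
and offset cancel. 64 levels balances intensity resolution against the
sparsity of a $N_g \times N_g$ co-occurrence matrix estimated from a few
hundred voxels; `n_levels` is configurable.

**Feature extraction.** The 25-feature panel:

* 3 *global* features from the histogram of quantized levels: Global
  Variance, Skewness, Kurtosis (population central moments; Kurtosis is
  non-excess, so a normal distribution gives 3; Skewness and Kurtosis are
  undefined on a constant ROI and reported as missing, never as 0, since a
  silent zero would bias the group statistics).
* 9 *local* features from the gray-level co-occurrence matrix (GLCM):
  Energy, Contrast, Entropy (base-2 logarithm), Homogeneity, Correlation,
  Sum Average, Variance, Dissimilarity, Autocorrelation. Pair counting is
  symmetric (each pair enters as both $(i,j)$ and $(j,i)$), so the marginals
  coincide and Correlation is well defined whenever the marginal variance is
  positive.
* 13 *regional* features from the gray-level run-length matrix (GLRLM):
  SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV.
  A run is a maximal sequence of consecutive collinear valid voxels sharing
  one level; runs break at the grid edge, at rejected voxels and at level
  changes.

The exact formulas are spelled out in `?glcm_features` and
`?glrlm_features`; they are the package's normative contract and are pinned
by closed-form unit tests and by brute-force enumeration oracles.

## Rotation-invariant direction averaging

A single GLCM and GLRLM per ROI is formed by averaging directional matrices,
so features do not depend on patient orientation:

* **2D** (circular ROIs): the four in-plane directions 0°, 45°, 90°, 135°,
  averaged with equal weights. The set is closed under quarter-turn
  rotations and mirror flips, which makes the averaged matrix — and hence
  every feature — exactly invariant under those transformations (verified to
  $10^{-9}$ in the test suite).
* **3D** (spherical and external ROIs): the 13 unique directions of the
  26-neighborhood (3 axis, 6 face-diagonal, 4 space-diagonal; antipodal
  offsets are redundant because pair counting is symmetric and run scanning
  is direction-reversal invariant). Axis, face and space steps have
  different physical lengths ($1, \sqrt2, \sqrt3$ voxels), so the matrices
  are averaged with weights proportional to $1/\lVert d\rVert_2$, normalized
  to sum 1. Weights depend only on $\lVert d \rVert$, which makes 3D
  features invariant under axis permutations of the grid.

Each directional GLCM is normalized to sum 1 *before* averaging, so sparse
directions are not over- or under-weighted by their pair counts. A direction
with no valid pair at all (possible in tiny or hole-riddled ROIs) is dropped
and the remaining weights renormalized; if no direction has a pair the ROI
is degenerate and its GLCM features are reported missing. GLRLM needs no
such rule — any valid voxel is at least a run of length 1 in every
direction. The co-occurrence step distance is fixed at one voxel; radii are
interpreted isotropically in voxel units, matching the convention of
specifying ROI radii "in pixels" even on mildly anisotropic grids.

## ROI geometry conventions

Voxel coordinates are 1-based array indices (R's native array semantics),
used consistently in function arguments and in the centers CSV. A voxel
belongs to a disc/ball when the Euclidean distance between voxel centers is
$\le r$ — the inclusive boundary rule; both choices are stated because
different tools disagree and the voxel count (29 for a disc of $r=3$, 123
for a ball of $r=3$) depends on them. ROIs that would be clipped by the
volume boundary are refused rather than silently truncated, because a
truncated ROI changes its feature statistics. Circular ROIs default to
fixing axis 2 (the coronal axis under the default axis labelling), where
hippocampal cross-sections are conventionally assessed.

## Group statistics

For every (ROI, feature) the cohort is screened twice: a one-way ANOVA
F-test across all groups, and two-sided Mann-Whitney-Wilcoxon (MWW) tests
for each pair of groups, the latter because a significant F only says *some*
pair differs, and because rank tests are preferable at modest group sizes.
The MWW implementation uses the exact null distribution when the combined
sample is at most 12 without ties, and the normal approximation with tie and
continuity corrections otherwise.

Both Bonferroni (family-wise error) and Benjamini–Hochberg (false discovery
rate) corrections are applied at $\alpha = 0.05$. The correction family
defaults to *one ROI × one comparison* (the 25 features), making per-ROI
significance counts comparable across ROIs; `family = "global"` pools all
tests instead. The family choice is genuinely open — per-ROI counts cannot
disambiguate it — so it is exposed as a parameter rather than hidden.
Missing feature values are dropped per test, never imputed; a group left
with fewer than two usable values makes that test missing. Adjusted
p-values are never below raw ones, and the significance flags are monotone
(Bonferroni ⊆ BH ⊆ raw), which the suite checks on random p-vectors.

ANOVA is run on raw feature values without transformation. One edge case is
resolved conservatively: $\alpha$ must lie strictly inside $(0, 1)$.

## The phantom generator

Synthetic cohorts make the full pipeline testable without clinical images.
Each phantom volume is

$$ I(\mathbf{v}) = m + g\,v_1 + (G_\sigma * \varepsilon)(\mathbf{v}), \qquad
\varepsilon \sim \mathcal N(0, s^2) \ \text{i.i.d.}, $$

white Gaussian noise of standard deviation `noise_sd` ($s$), optionally
convolved with a Gaussian kernel $G_\sigma$ of FWHM `smooth_fwhm_vox`
voxels, plus a mean level $m$ and an optional linear ramp $g$ along the
first axis. Smoothing is the texture knob: it injects spatial
autocorrelation with an analytically known correlation length, so its effect
direction on the features is predictable — GLCM Correlation and Homogeneity
rise, Contrast and Dissimilarity fall. The suite verifies that mean GLCM
Correlation of a centred radius-5 sphere increases strictly over FWHM
$\{0, 1, 2\}$.

Default conditions emulate the motivating three-group study design: 35
subjects per group (CN, EMCI, AD), two seed points per volume admitting
radius-8 spheres, identical CN and EMCI texture (FWHM 0) and a smoothed AD
texture (FWHM 2, `noise_sd` 10, mean 100, no ramp) — so AD differs from both
other groups while CN and EMCI are exchangeable. These defaults were fixed
once, as a realistic strong-effect scenario, and are not tuned per test.

Determinism: volumes are generated with R's Mersenne-Twister generator; a
per-subject sub-seed stream is drawn once from the cohort seed, so the same
spec reproduces bit-identical volumes and any subject can be regenerated
independently. Gaussian smoothing is separable shift-and-add with the kernel
truncated at $3\sigma$ and zero padding — near the faces the smoothed noise
variance dips, which is harmless here because ROIs sit in the interior.

What the phantoms do **not** emulate: anatomy, bias fields, motion, partial
volume, Rician noise, or inter-subject intensity scale differences. Passing
tests therefore demonstrate correctness of the computational pipeline and
calibration of its statistics, not clinical performance on real MRI.

## Numerical and degenerate-input choices

* Constant ROIs: all levels collapse to 1; Energy = Homogeneity = 1,
  Contrast = Entropy = Dissimilarity = Variance = 0; Correlation, Skewness,
  Kurtosis are missing.
* The GLRLM run-length axis extends to the longest grid extent of the ROI
  bounding box; averaged run counts are real-valued because of the direction
  weights.
* Feature tables serialize missing values as literal `NA` cells and
  round-trip to full double precision.
* NIfTI `scl_slope`/`scl_inter` are honoured on read (verified against a
  hand-written scaled file in the tests); orientation metadata labels axes
  but never triggers resampling. Voxel spacings are rounded to 7 significant
  digits to absorb float32 pixdim storage noise.

## Problem sizes used by the checks

The test suite and the acceptance script run the whole pipeline at reduced
but fixed sizes chosen to exercise every code path with stable statistics:
oracle comparisons on grids up to $6^3$ with $N_g \le 4$; invariance checks
on smoothed $13^3$–$17^3$ phantoms; a full 35-per-group cohort with all 12
ROIs per subject for the headline run; 200 null cohorts (10/group, one seed
point, radius 3) for FDR calibration; and 50 effect cohorts (20/group,
radius 5) for power. At these sizes the whole suite completes in a few
minutes on one core.

## Limitations

Equivalence with any particular MATLAB radiomics implementation is not
guaranteed: texture feature definitions vary across packages (notably the
Sum Average convention, the 3D weight normalization, and inclusive vs
exclusive disc boundaries), and the choices here are pinned by this
package's own tests rather than by cross-software comparison. The pipeline
performs no segmentation: seed points (or an external binary mask) are
inputs. Multi-distance GLCM analysis, gray-level size-zone matrices, LBP and
wavelet textures are out of scope.
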