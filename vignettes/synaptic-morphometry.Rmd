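---
title: "Measuring synaptic clefts, boutons and vesicle pools: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synaptic clefts, boutons and vesicle pools: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmorph)
```

# Scope

`synmorph` quantifies the ultrastructure of symmetric (inhibitory)
synapses formed by Purkinje-cell recurrent axon collaterals on
neighbouring Purkinje cells, and the morphology of the boutons that
carry them. It covers four measurement families — synaptic cleft width
from electron-microscopy (EM) line profiles, bouton detection and voxel
volumetry from confocal z-stacks, spatial bouton density over
superimposed arbors, and geometric vesicle classification around active
zones (AZ) — plus the statistical procedures used to compare genotypes
(pooled *t*, two-sample Kolmogorov–Smirnov, Hartley F~max~
homoscedasticity). Because no public micrographs accompany this kind of
study, every measurement stage is paired with a synthetic-data generator
that produces inputs with analytically known ground truth; the test
suite exercises recovery of that truth.

# The standardized cleft-width estimator

## Model

Across an EM cross-section of a symmetric synapse, electron density
shows two membrane peaks flanking a brighter cleft valley. The cleft
boundary is poorly defined by eye, and the naive peak-to-peak distance
overestimates the cleft because it includes part of both membrane
densities. The standardized estimator therefore works in three steps:

1. **Line sampling.** Five parallel straight lines of 100 nm length are
   traced across the cleft, perpendicular to the membranes, spaced
   10 nm apart along the membrane tangent (`sample_cleft_lines()`;
   count, length and spacing are parameters with those defaults).
   Intensities are read by bilinear interpolation at 1-nm steps.
2. **Averaging.** The five profiles are averaged pointwise
   (`average_profiles()`). For i.i.d. noise this reduces the variance
   by 1/5 and stabilizes the valley between the peaks.
3. **Drop rule.** On the averaged profile, `measure_cleft_width()`
   finds the two membrane peaks and the valley minimum between them.
   Walking from each peak towards the valley, the boundary is the first
   point where the density has dropped by 10% of that peak's
   peak-to-valley range; the width is the distance between the two
   boundaries, with sub-sample precision by linear interpolation.

The conventional manual measurement (`measure_cleft_manual()`) is the
peak-to-peak distance. Since the drop boundaries lie strictly between
the peaks, the manual width is never smaller than the standardized one
— an ordering asserted property-style in the tests.

## Interpretation choices

Two points in the verbal definition of the drop rule are genuinely
open, and the package fixes them explicitly:

* **"Decreased by 10%"** is interpreted as 10% of the peak-to-valley
  dynamic range, matching profiles normalized to peak/valley. The
  alternative reading — 10% of the absolute peak value — is available
  via `drop_mode = "absolute"`. The two coincide when the valley is at
  zero and differ otherwise.
* **Walking direction.** The boundary is the *first* crossing walking
  from the peak towards the valley, i.e. the inner face of the membrane
  density nearest the cleft. Taking the last crossing instead would
  bind the boundary to the valley floor and make it noise-sensitive.

## Peak detection

Peaks are found structurally rather than by thresholding alone: the
global density maximum is one membrane; the second membrane is the
highest local maximum separated from the first by a valley at least
`prominence_floor` (default 10%) of the profile range deep. Smaller
maxima — noise ripples riding on a membrane flank — are ignored rather
than treated as competing membranes, because their separating dip is
shallow. A profile with no qualifying second peak raises a classed
"ambiguous synapse" error; a flat profile raises a degenerate-profile
error. Equal-height candidates are resolved towards the anchor
midpoint. This tolerance for sub-floor maxima is deliberate: at the
noise level used in the robustness tests (SD = 10% of the range),
single noisy lines routinely carry small spurious maxima, and a
measurement that refused all of them would leave nothing for the
averaging comparison to improve on.

## Sampling defaults

The sampling step along each line defaults to 1 nm (the nominal EM
pixel pitch at the magnification this kind of material is imaged at);
all boundary positions are reported at sub-step precision. The recovery
contract is correspondingly "within one sampling step": on noise-free
synthetic profiles spanning true widths of roughly 15–35 nm the
estimator must land within 1 nm of the analytic drop-rule width.

# Synthetic EM data

`gen_cleft_profile()` builds a 1D electron-density profile from two
membrane cross-sections (triangular ramps or Gaussians) of density
`peak_density` over a valley of `valley_density`, separated by a known
peak-to-peak distance inside a 100-nm window. Noise is additive
Gaussian, clipped at zero — the simplest model sufficient for testing
the 1/n variance reduction of averaging; no attempt is made at
photorealistic EM texture, stain gradients or correlated grain.
Profiles are produced in electron-density polarity (membranes high)
to match the estimator's peak/valley language; `invert = TRUE` on the
measurement side handles bright-membrane data.

Ground truth is the drop-rule width evaluated on a 0.01-nm grid of the
analytic noise-free profile. For triangular membranes this equals the
closed form (separation − 2 × drop × ramp half-width) and the tests
also check it against an independent root-finding oracle for Gaussian
membranes.

`gen_em_patch()` extrudes the profile into a 2D image, optionally
bowing both membranes along a circular arc, and returns the anchor a
user would click; membranes leaving the patch under excessive curvature
is a validation error, not a silent truncation.

# Bouton detection and volumetry

## The twice-diameter rule

A bouton is operationally a stretch of collateral whose local diameter
exceeds twice the axon's baseline diameter. `local_diameter_profile()`
measures, at each skeleton point of an input trace, the contiguous
foreground extent along the in-plane normal on the nearest z-slice.
The reference "axonal diameter" is not defined at a particular point
anywhere in the verbal rule, so the package takes the median diameter
over non-candidate positions (those within 1.5× the global median) —
a robust estimate that ignores the dilations being detected.
`detect_boutons()` then finds the crossings of diameter =
2 × baseline, interpolated linearly in arc length; a dilation still
above threshold at the end of the trace closes as a *terminal* bouton
at the trace end (one crossing only).

## Voxel counting

`bouton_volume()` counts voxels above threshold whose projection onto
the trace falls inside the bouton's arc interval (half-open, so
adjacent intervals partition voxels exactly) and multiplies by the
voxel volume. On the default 0.01 × 0.01 × 0.4 μm grid the quantum is
0.00004 μm³. The threshold defaults to Otsu's method on the stack
(fluorescent-voxel counting needs *some* threshold and none is implied
by the verbal rule); any fixed numeric threshold can be supplied, and a
radius-1 median filter per slice is available to mirror standard
pre-measurement denoising.

The synthetic stack generator rasterizes a straight tube plus spherical
dilations on the anisotropic grid. Its per-bouton ground truth reports
the analytic sphere volume, the sphere/tube overlap (numerically
integrated on a transverse grid 10× finer than the in-plane voxel
size — the z spacing is 40× coarser and would dominate the error if
used), and their difference. The coarse 0.4-μm z-step is the binding
accuracy constraint: a rasterized 1-μm sphere recovers its volume to
about 2%, and the acceptance contract allows 5%. Real confocal data
additionally suffer a point-spread function and depth attenuation that
the generator deliberately does not model; passing these tests shows
the counting geometry is right, not that segmentation of real stacks is
solved.

# Density maps

`align_arbors()` applies to each cell the rigid transform that brings
its soma to the origin and its main-axon direction onto a common target
direction; no scaling and no reflection, so mirror-image arbors remain
mirror images and pairwise distances are preserved exactly.
`bin_density()` counts points in half-open 20-μm square bins (a
Purkinje soma diameter) anchored at the common soma origin, so the soma
sits at a bin corner and matrix indexing is reproducible; a point on a
bin edge belongs to the higher-index bin. Densities are counts/bin
area in boutons/μm². No smoothing is applied before rendering:
`render_heatmap()` shows the raw matrix with the warmest colour at the
maximum.

# Vesicle classification

The AZ is treated as a straight chord (its length is a single number
per AZ, so curvature is ignored). Two pools are counted:

* **vicinity** — vesicle centre inside the half-disc of diameter equal
  to the AZ length, centred on the AZ midpoint, on the presynaptic
  side;
* **docked** — vesicle membrane (centre distance minus radius) closer
  than 10 nm to the chord, within the chord's lateral extent. The
  membrane-based distance is the default because a docking criterion
  phrased as distance from the plasma membrane most plausibly refers to
  the vesicle surface; `from = "center"` switches to centre-based.
  Docked vesicles always count in the vicinity pool.

Vesicle density is the vicinity count divided by the half-disc area,
reported per (100 nm)² = 10⁴ nm². Literature figures quoted "per
100 nm²" cannot be literal square nanometres at half-disc areas of
10⁴–10⁵ nm²; the unit is therefore explicit in every output and no
comparison against such printed values is attempted. The count–length
relationship is summarized by an OLS fit with Pearson *r* and its
two-tailed *p*; both *r* and *r*² are always reported because figure
legends sometimes label the plain correlation "coefficient of
determination".

# Statistics

* `ttest_two_sample()` defaults to the pooled-variance Student test
  (the named procedure in this literature); Welch is one flag away.
* `ks_two_sample()` computes the exact supremum distance between the
  empirical CDFs and the asymptotic two-sided p value; both are
  cross-checked against R's implementations to 10⁻¹⁰ in the tests.
* `fmax_test()` forms the ratio of the largest to smallest subgroup
  (per-mouse) variance and compares it with the Hartley critical value
  at α = 0.05. The embedded table covers k = 2…12 groups and
  df = 2…60 (interpolated in 1/df between tabulated rows); the k = 2
  column is analytically `qf(1 − α/2, df, df)`, and random cells of the
  table were verified against large Monte-Carlo null simulations.
  Out-of-table settings use a seeded Monte-Carlo estimate (10⁵
  replicates) and the output records which route was taken. With
  unequal subgroup sizes, df is taken as the rounded mean size minus
  one — Hartley's test assumes balance, and the choice is recorded in
  the result rather than hidden.
* `cv_paper()` implements the study's stated coefficient of variation,
  `sqrt(SD/mean)`. That definition is non-standard and dimensionally
  odd, but it is what the source text defines, so it is the verbatim
  default; the conventional SD/mean sits behind
  `variant = "conventional"` and the variant used is always part of
  the output.
* `geometry_comparison()` carries group means through the derived
  geometry: contact area as a disc on the AZ length, cleft volume as a
  cylinder of that base and the cleft width as height, with percent
  differences for length, area, width and volume.

# Problem sizes and numerical tolerances

The test and acceptance workloads are sized to run comfortably on one
CPU: 200 synthetic profiles for the noise-free recovery sweep and for
the paired averaging-versus-single-line comparison (5 replicates each,
Wilcoxon signed-rank at p < 0.01); stacks of roughly 4 × 3 × 2.4 μm
(≈ 10⁶ voxels) for volumetry; 100 random vesicle scenes against a
brute-force geometric oracle; 200 uniform Poisson patterns (≈ 10
points per bin) for the binning dispersion check; 500 simulated
equal-variance datasets (k = 2, n = 16) for the F~max~ type-I error,
which must land in [0.02, 0.09] at α = 0.05. Recovery tolerances are
one sampling step (cleft), one in-plane voxel (diameters), 5%
(sphere volumetry) and exact agreement (vesicle counts, bin
conservation, additivity, scale covariance).

# Known limitations

* Anchors, traces and vesicle coordinates are *inputs*: the package
  does not find synapses, skeletonize axons or detect vesicles in raw
  images.
* The generators do not model point-spread functions, photorealistic
  EM texture, correlated noise or membrane curvature beyond a circular
  arc; conclusions from passing tests are about measurement geometry,
  not about segmentation robustness on real micrographs.
* Printed critical-F~max~ values from any particular study cannot be
  reproduced without knowing the exact (k, n) used there; the package
  reports its own lookup parameters instead.
* The cleft estimator assumes exactly two membranes in the 100-nm
  window; triadic or obliquely cut profiles raise errors rather than
  guessing.
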