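---
title: "Observer-independent cytoarchitectonic mapping: models, statistics and design choices"
author: "cytoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer-independent cytoarchitectonic mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoarch)
```

Cortical areas differ in their cytoarchitecture: the density, size and
laminar arrangement of neuronal cell bodies. Drawing area borders by eye is
observer-dependent; this package implements the quantitative alternative in
which borders are positions where the *laminar density profile* of the
cortex changes significantly, together with the downstream statistics a
mapping study needs (volumetry, probabilistic maps, inter-areal
similarity). This vignette explains each model, its assumptions, the
parameters that matter, and the design decisions taken where the procedure
is conventionally underspecified.

## 1. From a stained section to laminar profiles

**GLI images.** The Grey Level Index is the areal fraction of cell-body
pixels in a small window of a binarized, cell-body-stained section; it is a
proxy for cell packing density. `compute_gli()` averages non-overlapping
16 × 16 px windows by default (window and stride are configurable, source
resolution defaults to 1.02 µm/px). Because windows are non-overlapping,
the mean of the GLI image equals the foreground fraction of the
window-aligned region *exactly* — this conservation is asserted in the test
suite. Trailing partial windows are dropped rather than padded.

**Depth coordinate.** Profiles must be sampled along traverses that run
from the outer contour (the layer I/II border, depth 0) to the inner
contour (the layer VI/white-matter border, depth 1) without crossing each
other. On curved cortex "vertically oriented" is ambiguous, so
`solve_depth_field()` solves the Laplace equation over the ribbon with
Dirichlet values 0 and 1 on the two contours and no-flux conditions on the
cut edges. Harmonic fields have no interior extrema, so gradient
streamlines connect the contours and never cross; on a flat ribbon they
degenerate to straight vertical lines (the solver reproduces the linear
ramp to ~1e-14). The discrete system (5-point stencil, direct sparse
solve) is exact up to the rasterization of the contours: Dirichlet cells
form one-cell-wide jagged bands, so against the closed-form log-radial
solution on an annulus the field is accurate to about a quarter of a grid
cell (max ≈ 8e-3, RMS ≈ 2e-3 at a 35–40-cell thickness) once the
effective boundary radii are accounted for. Sub-cell boundary stencils
would buy another order of magnitude but are not needed at the accuracy
the border statistic requires.

**Profile extraction.** `extract_profiles()` seeds traverses at equidistant
arc-length positions along the outer contour, integrates the normalized
depth-field gradient with midpoint (RK2) steps of a quarter cell, and
samples the GLI by bilinear interpolation at 100 equidistant normalized
depths (`depth_bins`, configurable; the profile length normalization is a
convention, not physics). A traverse whose streamline leaves the ribbon is
excluded and reported, never silently interpolated.

## 2. The border statistic

Each profile y(x) is summarized by ten central-moment features: mean
density, depth centroid Σxy/Σy, weighted standard deviation, skewness
(standardized by σ³) and kurtosis (by σ⁴), plus the same five features of
the profile's first derivative. Derivative weights are the *absolute*
first differences |Δy|, because weighted moments require non-negative
weights. Degenerate cases are explicit: an all-zero profile is an error; a
zero weighted σ reports skewness/kurtosis 0 with a warning; an all-flat
derivative reports centroid 0.5 and zero spread with a warning.

At a candidate border after traverse k, two adjacent blocks of b profiles
([k−b+1, k] and [k+1, k+b]) are compared by the Mahalanobis distance
between their mean feature vectors under the pooled within-block sample
covariance,

MD² = (m₁ − m₂)ᵀ S⁻¹ (m₁ − m₂),

and significance is assessed by the two-sample Hotelling T² = (b/2)·MD²
via the exact F transform, F = (2b − p − 1)/((2b − 2)p) · T² with
df (p, 2b − p − 1) and p = 10 features, Bonferroni-corrected over the
number of sliding positions. Averaging feature vectors over blocks raises
the signal-to-noise ratio; sliding k over the ribbon yields the distance
function whose significant local maxima are candidate borders.

`detect_borders()` repeats this for every block size in 12–24 (the
protocol's stated range; a narrower 16–24 variant exists in the field, and
the range is configurable), then requires *consensus*: candidates from
different block sizes within `merge_window` traverses are merged (reported
position: their median) and kept only when supported by at least
`min_support` block sizes (default: half the admissible sizes, rounded
up). Consensus across block sizes replaces a second multiplicity
correction across scales.

Numerical and procedural choices:

* **Covariance.** Pooled within-block sample covariance; with b ≥ 11 > p/2
  per block the pooled matrix (2b − 2 df) is generically invertible.
  Optional shrinkage toward a scaled identity, S ← (1−λ)S + λ·tr(S)/p·I,
  handles near-singular data and permits b ≤ p; default λ = 0. Blocks with
  identical means (a noise-free homogeneous ribbon) are distance 0 by
  definition and skip the solve.
* **Bonferroni scope** is per block size, across sliding positions.
* **Plateaus** of the distance function are collapsed to their midpoint;
  for equal maxima the lower traverse index wins.
* **merge_window = 5.** Significant maxima of different block sizes around
  one border spread by a few traverses; a window of 3 occasionally splits
  them into duplicate borders (≈2% of three-area ribbons in simulation),
  while 5 merges them reliably and stays far below the narrowest
  admissible area width (12 traverses).
* **alpha = 0.001** on corrected p-values, the protocol's level.

Calibration is verified rather than assumed: under a multivariate-normal
null the Hotelling p-values are uniform (KS test) with type-I error at
nominal level, homogeneous ribbons of 162 traverses produce a border in
≈0% of seeds (criterion: ≤2%), and two-area ribbons with a 0.15-GLI
contrast in two layers at noise sd 0.03 are recovered within ±3 traverses
in ≥95% of seeds.

## 3. What the synthetic generator does and does not emulate

Real input data are post mortem histological sections; none are shipped.
The generator produces, with known ground truth:

* **Laminar models** — piecewise-constant density over normalized depth
  (five layers in the defaults), optionally smoothed by a moving average to
  mimic gradual laminar transitions, with i.i.d. additive Gaussian GLI
  noise clipped to [0, 1]. The default "agranular vs dysgranular" pair
  differs by 0.15 GLI in layers II and IV; the noise sd of 0.03 is a
  deliberately conservative guess (the protocol reports no noise
  magnitudes; the value is exposed in the config).
* **Ribbons** — segments of traverses per area with borders at the segment
  boundaries (162 traverses, border after 76 in the demo).
* **Cell images** — Bernoulli pixels whose success probability follows the
  laminar model between two contours, flat or bent into an annular sector.
* **Subject label volumes** — a canonical disjoint area layout displaced
  per subject by a rigid integer-voxel translation (jitter sd 2 mm by
  default), standing in for individually mapped brains already warped to a
  common space.

Not emulated: cell morphology and staining artefacts, section-to-section
registration errors, nonlinear warps, layer-specific noise correlations,
and the biological within-area gradients of real cortex. Passing tests
therefore demonstrate the *statistical machinery* — calibration,
invariances, ground-truth recovery under the stated conditions — not
performance on real histology.

## 4. Volumetry

`cavalieri_volume()` implements the section-based estimator
V = Σareas × thickness × interval × shrinkage (20 µm sections, every 15th
measured, per-brain shrinkage factor supplied, not estimated). It is exact
up to the slab approximation: on an analytic sphere of radius 10 mm at the
protocol's spacing the error is <0.01%.

Group comparisons run on volumes expressed as fractions of whole-brain
volume, removing brain-size differences. `permutation_test()` uses the
mean difference as statistic and the add-one Monte Carlo estimator
p = (1 + #extreme)/(n_perm + 1) (never exactly 0; n_perm defaults to
10 000). Hemispheres come from the same brain, so the hemisphere factor is
tested by sign-flipping within-brain differences (paired); gender is
unpaired on per-brain mean fractions. The pooled values are sorted before
the Monte Carlo draws so that p is exactly invariant to group order and to
adding a constant. Correction across areas is Benjamini–Hochberg FDR by
default with Bonferroni selectable — the protocol names both, and FDR is
the less conservative, more standard choice for a handful of areas.

## 5. Probabilistic maps and the maximum probability map

`build_pmap()` counts, per voxel, the subjects labelling it as an area;
probabilities are exact multiples of 1/n_subjects. Affine mismatches are
errors — no silent resampling. `centre_of_gravity()` is the
probability-weighted mean of the world coordinates of the non-zero voxels.

`build_mpm()` assigns each voxel to the area of highest probability, with
two refinements. Ties go to the tied area with the highest mean
probability over the voxel's neighbourhood (26-connectivity radius 1 by
default, centre excluded; 6/18 selectable — the notion of "neighbouring
voxels" is a convention); a tie surviving that falls to the lowest area
index and is counted in the output. The 40% rule is applied only at
*unmapped* borders: where no competing area has non-zero probability, a
winner below `unmapped_threshold = 0.4` is left unassigned, whereas a
sub-threshold winner that beats a mapped competitor keeps the voxel (the
rule exists to trim speculative outer borders, not to punch holes between
mapped areas — this reading is the main interpretive choice and is
configurable).

`correlate_maps()` is the Pearson correlation of two maps' voxel values.
The domain is the main free parameter: the default is the union of both
maps' non-zero voxels (whole-grid optional). Published correlation tables
depend on this choice, so identical numbers cannot be expected without
knowing the original domain. `assign_coordinate()` reports all areas whose
probability at the containing voxel reaches 0.2, descending — coordinates
outside the grid yield an empty assignment with a warning.

## 6. Inter-areal similarity

`mean_area_feature()` characterizes an area by the elementwise mean of the
feature vectors of 45 profiles from each of 3 sections (sampled without
replacement, seeded). Euclidean distances between these 10-vectors feed
two descriptive views:

* **Metric MDS** (`mds_embed()`): least-squares scaling minimizing
  stress-1 = √(Σ(d̂ᵢⱼ−dᵢⱼ)²/Σdᵢⱼ²) by iterative majorization (Guttman
  transform), initialized from classical scaling plus 7 random restarts
  (SMACOF-style; the flavour behind published stress values is rarely
  stated, and least-squares metric scaling is the natural reading for
  quantitative distances). Exactly 2D-embeddable inputs reach stress
  <1e-6; the 4-point unit simplex reproduces the independently optimized
  stress 0.1691 to 1e-3.
* **UPGMA** (`upgma_tree()`): arithmetic-mean linkage with node height =
  merge distance/2, hence an ultrametric tree whose cophenetic distances
  reproduce ultrametric inputs exactly. Ties between closest pairs merge
  the lexicographically smallest label pair and are counted. Newick export
  encodes the ultrametric branch lengths; an unrooted rendering is a
  display choice that does not alter the topology.

Feature standardization before distances is off by default (the published
procedure does not mention z-scoring) but exposed, because the ten
features live on different scales and scale dominance is a real concern.
Per-hemisphere versus pooled-area vectors are both supported — the
published pooling is ambiguous.

## 7. Reproducibility and problem sizes

Every stochastic step takes a seed; the demo pipeline (`run_pipeline()`)
derives per-stage seeds from one master seed and reruns byte-identically.
Test and acceptance workloads are sized to run on one CPU in a few
minutes: 100-seed border recovery and 200-seed specificity on 162-traverse
ribbons, 2000-replicate Hotelling calibration, 50 random 20³ pmap families
against a brute-force argmax oracle, 200-seed null volumetry at 1000
permutations, and 50-seed two-family clustering. These sizes are the
package's own choice of simulation budget; all rates they estimate are
stable well beyond the margins asserted.

## 8. Known limitations

* The depth-field solver is first-order accurate at rasterized contours;
  very thin ribbons (<8 GLI cells across) lose depth resolution.
* Border detection assumes profiles are ordered along the ribbon with
  roughly constant spacing; it does not model gaps from excluded
  traverses.
* The MPM tie-break examines a single-voxel-radius neighbourhood; large
  plateaus of exactly tied probabilities (possible with few subjects) can
  cascade to the lowest-index rule.
* Volumetry treats the shrinkage factor as exact; its estimation error is
  not propagated.
* Synthetic validation does not certify performance on real histology
  (Section 3).
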