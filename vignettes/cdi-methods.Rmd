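---
title: "Methods: the lateral tibiofemoral cartilage damage index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lateral tibiofemoral cartilage damage index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdi)
```

# The measurement model

The cartilage damage index (CDI) replaces whole-surface cartilage
morphometry with thickness measurements at a small, fixed set of
*informative locations*. Its premise is that full-thickness cartilage loss
(denudation) in the lateral tibiofemoral compartment concentrates in a
reproducible posterior region of both articular surfaces, so a 3 × 3 grid
of measurement points per surface, placed over that region once during
development, captures most of the clinically relevant damage signal at a
tiny fraction of the reading effort.

## Surface coordinates

Each surface (distal lateral femur, proximal lateral tibia) gets a
rectangular universal coordinate system on the sagittal stack:

* `v` (medial → lateral): linear in slice index between the most medial and
  most lateral slices containing bone. `slice_for_v()` rounds half-steps
  toward the lateral slice — an arbitrary but fixed and documented
  tie-break.
* `u` (anterior → posterior): linear in image column along the slice's
  bone–cartilage boundary, normalized **per slice** so that each slice's own
  anterior and posterior boundary extremes map to 0 and 1. The per-slice
  normalization (rather than a global anterior-posterior bounding box) is a
  design choice: it projects each slice's boundary onto the full axis the
  way a per-slice reading does, and is robust to condylar curvature, at the
  price that equal `u` on different slices does not mean equal physical
  anterior-posterior position.

The boundary itself is extracted from label masks: per column, the bone
voxel facing the articular side (superior for the tibial plateau, inferior
for the femoral condyle), keeping the largest contiguous column run.
Degenerate inputs error early and explicitly: a volume with no bone
("empty volume"), bone confined to one slice ("degenerate medial-lateral
extent"), a boundary shorter than 3 points ("degenerate boundary").
`min_bone_voxels` (default 1) guards the bounding-slice scan against stray
labels.

Round-trip fidelity is exact by construction up to rounding: both index
maps are linear, so `(u,v) → (slice, col) → (u,v)` errors are bounded by
half a grid step per axis, and boundary-extreme columns map to exactly 0
and 1. The test suite verifies this exhaustively on rasterized phantoms.

## Atlas and informative locations

Denudation annotations from a development sample are projected into (u, v),
binned on a 100 × 100 cell grid (half-open cells; `u = 1` and `v = 1`
belong to the last cell), and accumulated into a per-cell knee count. The
published method says only that 9 locations per surface were selected
"evenly, in and around" the most frequent denudation region; the package
operationalizes this with four explicit parameters:

1. threshold the map at the 0.75 quantile of its **positive** counts;
2. keep the 8-connected component with the largest total count (ties go to
   the more posterior component, matching the lateral compartment's
   posterior damage pattern);
3. dilate the component's bounding box by `margin_uv = 0.05`, clipped to
   the unit square (the "around" part);
4. place locations at the cell centers of the even 3 × 3 partition of the
   box. The partition cells also define each location's u-cell for the
   length term, so the 9 cells tile the box without gaps or double
   counting.

All four knobs are configuration values, not constants; the defaults are
our choices, since no published values exist. Selection stability between
100 × 100 and 50 × 50 grids (within one coarse cell width) is asserted in
the tests. EBImage's labeling routine is 4-connected, so the 8-connected
component labeling is a small in-package BFS.

## Thickness, length, and the index

At each location, thickness is measured by casting a ray from the boundary
point nearest to `u` along the outward surface normal (estimated from the
boundary tangent over ±3 boundary points), sampling labels every 0.1 mm up
to a 15 mm cap (a guard against runaway rays through label noise), and
taking the cartilage-run length with interface positions refined to
transition midpoints. Because a binary label grid localizes an interface
only to a voxel edge, a single ray is quantized at the ~0.23 mm scale
(half the 0.456 mm row spacing); the package therefore averages a small
bundle of parallel rays (default 7, spaced 0.15 mm tangentially) — a
standard sub-voxel partial-volume mitigation. The residual single-location
error remains bounded by roughly half the in-plane voxel diagonal
(~0.3 mm) in the worst, grid-aligned case; tests assert a 0.35 mm bound
and a small mean bias, and the CDI-level closed-form oracle (below) is met
within 5%. Staircase notches — 1–3 sample gaps where a ray grazes voxel
corners — are merged into the run rather than treated as layer breaks.

The anterior–posterior length of a location is the physical extent of
cartilage-bearing boundary columns inside the location's half-open u-cell
on that slice, so denuded columns contribute no length and the 9 cells
never double-count.

The index is

$$\mathrm{CDI} = \sum_k t_k \, L_k \, m / h$$

with $t_k$ the thickness (mm), $L_k$ the cell length (mm), $m$ the
medial–lateral factor and $h$ height in meters; femur and tibia sum into
the tibiofemoral total. Two units decisions are ours, because the source
description ("the product of thickness, length, and voxel size, divided by
height") is ambiguous: $m$ is taken to be the **slice thickness** (0.7 mm),
making each term a volume in mm³, and height is in meters, so CDI is in
mm³/m. Absolute CDI magnitudes are therefore not comparable to published
tables — only the statistics built on them (correlations, ICC, SRM, trends)
are, and nothing in the package claims otherwise. A denuded location
scores thickness 0 (not an error); a height ≤ 0 or a surface with no
measurements is an error.

Two structural properties follow and are asserted as tests: scaling height
by $c$ scales CDI by exactly $1/c$, and a full-thickness lesion covering
one location cell removes exactly that location's contribution, while a
lesion disjoint from all cells changes the CDI by less than measurement
tolerance — the method's designed blind spot, which is a real limitation
of location-based indices, deliberately surfaced rather than hidden.

# The synthetic data

No patient data ships with or is required by the package; every claim the
tests make is exercised on synthetic knees with known ground truth.

## Phantoms (voxel route)

`rasterize_phantom()` builds one articular surface as labeled voxels at the
DESS-like default geometry (0.365 × 0.456 × 0.7 mm voxels, 307 × 384
matrix, 160 slices). The bone shapes are deliberately simple analytic
surfaces — a cylindrical cap for the femoral condyle (radial cartilage
band, so normal-ray measurement has an exact oracle) and a shallow
elliptic dish for the tibial plateau (near-vertical normals, per-slice
chords that vary medial-laterally, so the per-slice u normalization is
actually exercised). Cartilage occupies the band of offset
`0 < d ≤ t(u, v)` along the surface normal, where `t` is an arbitrary
non-negative thickness field; focal lesions are half-open (u, v)
rectangles removing a depth fraction (1 = denudation, recorded in a
separate boundary-voxel mask). Ground truth is the continuum volume
integral of the thickness field over the curved surface (exact quadrature
including the cylindrical $t^2/2$ term), against which voxel counts
converge — tested at two resolutions, with 5% agreement at the standard
spacing. Overflow (cartilage leaving the volume) and negative thickness
are errors, not warnings.

Tests rasterize reduced-extent phantoms (36–48 slices, roughly 100 × 120
to 140 × 170 in-plane) at the standard voxel spacing: the discretization
behavior under test depends on voxel size, not organ size, and these sizes
keep a full suite run under a minute of rasterization.

## Cohorts (fast route)

Cohort-scale experiments do not need voxels: `generate_cohort()` draws
per-surface (u, v) thickness grids directly (50 × 50 cells), which keeps a
full validation-design experiment in seconds. The generator emulates the
study designs it is used to mirror: knees stratified by lateral JSN grade
(default 25 per grade, the validation design; 5 per grade for the
reliability set), with

* mean thickness decreasing 0.35 mm per JSN grade step from healthy bases
  of 2.2 mm (femur) and 1.8 mm (tibia), between-subject SD 0.25 mm, and a
  mild central-thickening spatial profile — magnitudes chosen as realistic
  for knee cartilage and for roughly halving the index from grade 0 to 3;
* full-thickness hotspot lesions with grade-dependent probability
  (0.05 / 0.25 / 0.55 / 0.85), drawn inside the posterior hotspot
  u ∈ [0.55, 0.85], v ∈ [0.30, 0.60], widths uniform in [0.10, 0.22];
* a 24-month thickness loss drawn per knee from Normal(0.10, 0.12) mm,
  thickness floored at 0; heights drawn once per subject
  (Normal(1.68, 0.09) m) and reused at both visits, so measured change
  isolates cartilage change;
* KL grade derived stochastically from JSN; JSW and HKA generated by
  linear links from the standardized true baseline cartilage volume
  (JSW: 4.4 + 1.9 z ± 1.3 mm; HKA: 3.0 − 1.5 z ± 4.45°), calibrated to
  plausible marginal means and SDs and to the observed sign structure —
  wider joint space and less malalignment with more cartilage;
* remeasurement noise of SD 0.15 mm per location thickness; the
  reliability analysis re-measures the same knees twice with independent
  noise realizations.

Everything is reproducible from the cohort specification's single seed,
byte for byte.

What the generator does **not** emulate matters for interpreting green
tests: there is no MR signal (labels only, so segmentation error is out of
scope), no reader variation beyond additive thickness noise (no slice
selection or boundary-marking disagreement, which is why synthetic ICCs
run higher than published intra-rater values), no anatomy variation beyond
scale (no osteophytes, no partial-volume pathology), and lesions are
axis-aligned rectangles. Passing tests show the pipeline measures what it
defines correctly and recovers constructed effects; they do not certify
performance on clinical images.

One consequence is worth stating explicitly: the rank correlation between
total CDI and true cartilage volume in the default cohort hovers around
0.9. The two deliberate "confounders" — focal lesions, which the CDI
by design over-weights about tenfold relative to their share of total
volume, and height normalization — bound it there; on knees without
lesions and height-matched, the same correlation is near 1. This mirrors
the method's intent (damage sensitivity, not volume estimation).

# The validation statistics

* **ICC(3,1)** — two-way mixed, single measure, *consistency* (the standard
  Shrout–Fleiss reading of "3,1"), computed from the explicit ANOVA
  decomposition; a fixed shift between sessions does not reduce it, and
  zero total variance is an error. Tests pin it to a brute-force
  sum-of-squares oracle (|Δ| < 1e-9 over 50 random matrices) and to an
  `aov()` cross-check, and assert that it decreases monotonically as
  remeasurement noise grows.
* **SRM** — mean change over SD of change (n−1 denominator), sign
  preserved (negative = decline). Monte-Carlo tests recover −μ/σ at n =
  100 for effect sizes bracketing the responsiveness range of interest.
* **Spearman correlation** — Pearson correlation of average ranks, p from
  the t approximation with n − 2 df (adequate at the n ≈ 80–100 design
  sizes); an exact enumeration p is available for n ≤ 8. Invariance under
  strictly monotone transforms is tested.
* **Trend across ordinal grades** — the source names no test; we chose the
  Jonckheere–Terpstra statistic (rank-based, built for ordered
  alternatives) with a seeded two-sided label-permutation p (default
  10,000 permutations; the permutation count and seed are recorded in the
  report), and report the trend direction. A
  linear-regression-on-grade alternative sits behind `method = "lm"` for
  comparison. The statistic is pinned to an O(N²) counting oracle, null
  calibration is checked by simulation (rejection rate in [0.03, 0.07] at
  α = 0.05), and power is checked under a 4-grade monotone-mean design
  with 25 knees per grade.

`build_validation_report()` assembles all of the above per surface, plus
per-grade mean CDI tables and the rank pairs used for rank scatter plots,
and serializes them to JSON/CSV.

# Numerical and degenerate-input decisions

* Half-open binning everywhere a continuous coordinate meets a grid
  (lesion rectangles, atlas cells, location cells); ties at a boundary
  belong to the lower cell, and the closed endpoint 1 folds into the last
  cell.
* `slice_for_v` rounds half-steps toward lateral; `col_for_u` rounds
  toward posterior. Both are stated in the function contracts.
* Voxel indices are 1-based throughout, the natural convention in R;
  all (u, v) arithmetic is index-origin-free.
* An empty denudation mask projects to an all-zero cell mask (valid input:
  a knee without lesions); an all-zero *frequency map* is an error for
  location selection (there is no hotspot to select).
* The pipeline derives every stage seed from the master seed by fixed
  offsets and stamps each run with the seed and a configuration hash, so
  a rerun reproduces every numeric artifact byte for byte (asserted in
  tests).

# Known limitations

* Single-location thickness accuracy is voxel-limited (~0.3 mm worst
  case at the default spacing); the index-level aggregate is what meets
  the 5% oracle. Surfaces steeply inclined out-of-plane would need the
  normal estimated in 3D rather than in-slice.
* The informative-location selection rule is a reproducible stand-in for
  a manual choice; published location coordinates do not exist to compare
  against.
* Absolute CDI values depend on the medial-lateral factor interpretation
  (see above) and are not comparable across implementations that resolve
  the ambiguity differently.
* The blind spot is structural: damage outside all location cells is
  invisible to the index, and the tests demonstrate rather than hide this.
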