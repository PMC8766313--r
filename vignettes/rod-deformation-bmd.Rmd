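---
title: "Rod contour deformation and fusion BMD mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rod contour deformation and fusion BMD mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodmap)
```

`rodmap` measures two longitudinal quantities from serial postoperative
CT of a lumbopelvic closed-loop reconstruction: the permanent contour
deformation of the U-shaped rod, and the densification of the bony
fusion mass expressed as volumes of bone mineral density (BMD)
categories. This vignette explains the model behind each stage, the
parameters that matter, the synthetic phantom used for validation, and
the design decisions taken where the method left genuine choices open.

## Coordinate conventions

All world coordinates are DICOM-native LPS (X patient-left, Y
patient-posterior, Z patient-superior), in millimetres; voxel indices
are 0-based with `world = origin + orientation %*% (index * spacing)`.
One convention everywhere keeps landmark CSVs, meshes and transforms
interchangeable across formats (DICOM, NIfTI — converted from its RAS
affine — and NRRD).

## Segmentation and overlap evaluation

Implant and bone are segmented by inclusive HU bands
(`threshold_segment()`). Metal is far brighter than bone, so the
defaults for the phantom — metal ≥ 3000 HU, bone 226–3000 HU — are
unambiguous; on clinical data both bands are configuration values
because scanner, kernel and metal alloy shift them. Structures in
contact are separated by 26-connected component analysis
(`largest_components()`), ties broken deterministically by the smallest
linear index. Mask interiors are restored per axial slice by flood
fill from the slice border with 4-connected background (`fill_2d()`):
a 4-connected background cannot slip diagonally through an 8-connected
contour, so closed outlines hold while open (C-shaped) contours stay
unfilled. Rater agreement is quantified with the Dice similarity index;
`dice()` refuses two empty masks (the ratio is undefined) and any
geometry mismatch.

## Surface meshes and distance QC

`mesh_from_mask()` builds the cuberille surface — the voxel faces
separating foreground from background, i.e. the 0.5 iso-surface under
nearest-neighbour interpolation — triangulated with consistent outward
orientation. The surface is closed and watertight by construction and
its signed volume equals voxel count × voxel volume exactly, which
makes volume oracles sharp. Smoother iso-surfaces (marching cubes)
would change distance statistics by well under the voxel quantization
that dominates them; the cuberille choice keeps the geometry exactly
faithful to the mask it represents.

`surface_distance()` implements a Metro-style comparison: points are
sampled uniformly by area (default 10 samples/mm², deterministic under
`seed`; mesh vertices are always included so polyhedral extrema are hit
exactly), and each sample's exact point-to-triangle distance to the
other mesh is taken. Both the symmetric Hausdorff maximum `hd_max` and
the pooled mean `hd_mean` are reported, together with the per-direction
breakdown, because "mean Hausdorff distance" is used ambiguously across
tools; emitting both makes either reading reproducible. Geometry
reduction before comparison uses `clip_cuboid()`: triangles with any
vertex on the discarded side are dropped and the cut is left uncapped,
so caps never contribute samples.

## Landmark registration

`fit_rigid_landmarks()` is the closed-form Kabsch solution: centroid
subtraction, SVD of the cross-covariance, determinant correction to
exclude reflections. It errors on fewer than three landmarks, name or
order mismatches, and collinear configurations (second singular value
≈ 0). The RMS residual is reported and, with noisy landmarks,
approximates the landmark noise SD. Landmarks are ingested from a CSV
sidecar (`scan_id, name, x, y, z`) — anatomical point picking is a
manual step, deliberately outside the package. Masks are resampled into
the reference grid with nearest-neighbour interpolation (labels must
stay binary); meshes and points are transformed exactly.

## Rod centerline and deformation components

The rod is a tube, and its centerline is extracted from the voxel
graph rather than by iterative thinning: foreground voxels form a
26-connected graph weighted by physical edge length; a double BFS sweep
finds the two geodesically farthest voxels (the rod ends); voxels whose
geodesic eccentricity `d_A + d_B` exceeds the tube path length plus a
slack of three estimated radii are pruned — this removes screw stubs
(the 15 mm default prune depth) without any explicit branch tracing —
and the survivors are binned by geodesic distance (1 voxel bins), each
bin contributing its centroid. Level-set centroids are intrinsically
sub-voxel and, unlike raw 3D thinning skeletons, not jagged; the ends,
where level sets follow the spherical cap rather than the axis, are
trimmed (2.5 radii) and rebuilt by extrapolating the local PCA tangent
to the farthest voxel minus one radius, with a half-voxel compensation
for the partial-volume erosion of the outermost surface voxel. The
polyline is smoothed with a centred moving average (window 5) and
subdivided so consecutive points stay within 2 voxels. On a straight
synthetic tube the result deviates from the true axis by well under
half a voxel; on the phantom U-rod the arc length is within 2% of the
generating curve.

Deformation is reported between a mobile point (L2 right pedicle screw
tip, snapped to the nearest centerline point by default) and a fixed
point (caudal iliac screw tip, not snapped — it is a screw tip, not on
the rod), as per-axis absolute distances in the common reference frame:

\[ X_d = |\Delta x|,\quad Y_d = |\Delta y|,\quad Z_d = |\Delta z|,\quad
   3D_d = \sqrt{X_d^2 + Y_d^2 + Z_d^2}. \]

The components are axis components, not in-plane 2D distances: the
Euclidean combination formula forces this interpretation (in-plane
distances would each mix two axes and double-count terms). The
anatomical plane names attached to them (coronal/frontal for X, axial
for Y, sagittal for Z) are display labels only. `build_series()` adds
deltas relative to the first scan and their mean ± SD over the later
timepoints.

## HU→BMD calibration and the voxel FE fusion map

Calibration scans contain five cylindrical insertions of known density
(0, 0.05, 0.10, 0.15, 0.20 g/cm³). Mean HU per insertion (rim excluded
by a 2 mm margin to avoid partial volume) is regressed per scan —
`BMD = a + b·HU` — and the mean conversion curve averages the per-scan
coefficients. Averaging coefficients (rather than pooling points)
weights every calibration session equally regardless of how its HU
values spread; `pooled = TRUE` provides the alternative.

The fusion ROI is one axial slice, the midplane between the right L4
and L5 pedicle screw tip z-coordinates in the registered frame, chosen
by nearest slice center. `build_bmd_mesh()` makes one hexahedral
element per bone pixel (element volume Δx·Δy·Δz), computes per-element
BMD (clamped below at 0 g/cm³ — negative calibrated values mean
adipose tissue), and bins it into 10 categories. The category
representatives 0.00, 0.12, …, 1.12 g/cm³ are treated as labels with
midpoint bin edges; bins are half-open `[low, high)` so an exact edge
value goes to the higher (denser) category, the first and last bins
absorb the tails. `category_volumes()` converts per-category element
counts to cm³; row sums always equal the slice's total segmented bone
volume, a conservation property asserted in the tests.

## Reliability statistics

`spearman()` computes ρ as the Pearson correlation of average ranks
(ties get average ranks) with a two-sided t-approximation p-value and,
for n ≤ 8, an exact permutation p over all n! permutations.
Interpretation bands follow Evans: < 0.20 very weak, 0.20–0.39 weak,
0.40–0.59 moderate, 0.60–0.79 strong, ≥ 0.80 very strong.
`correlation_panel()` correlates every BMD category's volume series
against days after surgery and, when supplied, the Xd/Yd/Zd series,
flags significance at p < 0.05 with no multiplicity adjustment by
default (a Benjamini–Hochberg option exists), and counts the
very-strong categories. Constant series are flagged undefined rather
than silently dropped.

`icc_two_way_mixed_absolute()` estimates ICC(A,1) and ICC(A,k) from the
two-way ANOVA mean squares (MSR rows/subjects, MSC columns/raters, MSE
residual):

\[ ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},
   \qquad
   ICC(A,k) = \frac{MS_R - MS_E}{MS_R + \frac{MS_C - MS_E}{n}}, \]

with 95% confidence intervals by the standard F-distribution method
(Satterthwaite degrees of freedom for the upper bound; average-measure
bounds by Spearman–Brown step-up of the single-measure bounds). Zero
between-subject variance degenerates the estimator; it warns and
reports the arithmetic as computed.

## The synthetic phantom: what it emulates, what it does not

`phantom_spec()` describes a 96×96×80 voxel scene at 1 mm isotropic
spacing: a U-rod (radius 4 mm, 8000 HU) with two vertical legs bridged
by a semicircular arc; two pedicle-like screw stubs on one leg marking
the ROI levels and two iliac-like screws running through the bottom arc
into two cortical-shelled bone blocks (1200 HU shell, 300 HU interior);
a soft-tissue block (40 HU) in air (−1000 HU); and an ellipsoidal
fusion region whose interior HU ramps linearly from 100 to 1200 across
timepoints. Partial volume at every surface is rendered by ≥ 3×
supersampling, so rasterized volumes conserve analytic volumes within
2%. Per-timepoint rigid motion (bounded, deterministic by default) and
a programmed bending displacement of the mobile rod end (default ramp
to (1.5, 1.0, −10) mm — a dominant 10 mm caudal-forward bend with small
off-axis components so no deformation series is degenerate) are applied
before rasterization; Gaussian HU noise (default SD 10) is seeded and
reproducible bit-exact. The calibration scan synthesizes its insertions
from the line BMD = a + b·HU (defaults a = 0, b = 0.001), so a
closed-loop fit must recover (a, b) to numerical precision.

Two emulation choices deserve note. The 1 mm isotropic grid favours
geometric fidelity — sub-voxel closed-loop tolerances are meaningful —
while clinical series with 3.75 mm slice spacing are a supported
parameterization of the same generator. And the fusion ramp ends at
1200 HU (BMD 1.2 g/cm³) rather than inside the trabecular range so the
densification trajectory traverses the full category scale including
the top category, mirroring the multi-year growth of the densest
fusion volumes that the statistics layer is meant to detect.

The phantom does **not** emulate: anatomical pelvis shape, beam
hardening or metal artifacts, scanner-specific noise texture, patient
repositioning error beyond rigid motion, or screw loosening. Passing
the closed loops therefore demonstrates the correctness of the
computational chain — segmentation arithmetic, registration, centerline
geometry, calibration algebra, binning — not robustness to artifact
physics; clinical thresholds remain configuration.

## Numerical choices and degenerate inputs

* Thresholds are inclusive bands; an empty segmentation warns rather
  than errors (it is a legitimate result of a bad band).
* Component ties break on the smallest minimum linear index;
  permutation enumeration for the exact Spearman p is capped at n = 8
  (40,320 permutations).
* `dice()` on two empty masks, registration with < 3 or collinear
  landmarks, disconnected centerline masks, a zero calibration slope,
  and duplicate follow-up days are hard errors.
* The rod tip reconstruction compensates the ~half-voxel erosion of the
  outermost partial-volume surface voxel; the residual end error stays
  below one voxel, which bounds the per-timepoint error of the bending
  recovery.
* The pipeline sets one seed for everything stochastic (mesh-distance
  sampling, noise), and identical config + seed reproduces all CSV
  outputs byte-identically.

## Problem sizes used in the validation suite

The tests and the acceptance script run the phantom at its default
96×96×80 grid with 4 follow-up timepoints plus one calibration scan,
chosen as the smallest series that exercises the full longitudinal
logic (the Spearman precondition needs four scans) while every
closed-loop tolerance stays sub-voxel. The statistics layer is
additionally validated on the shipped 12-scan longitudinal volume
table and on simulated rater matrices up to n = 200 subjects.

## Known limitations

* Xd/Yd/Zd cannot separate the mechanical modes (axial load, shear,
  bending, torsion) producing them; only the resultant point-to-point
  geometry is observable from CT.
* Centerline curvature analysis and FE stress computation on the
  exported voxel mesh are out of scope (the VTK export is scaffolding
  for such work).
* The DICOM reader supports uncompressed Explicit VR Little Endian
  series only; convert anything else to NIfTI/NRRD first.
* The ROI is a single axial slice by design; volumetric fusion ROIs
  would need a different slice-selection rule.
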