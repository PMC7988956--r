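---
title: "Methods: statistical surface and averaged density modelling of the scaphoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical surface and averaged density modelling of the scaphoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carposhape)
```

This vignette is the package's own account of its models, the assumptions
behind them, the numerical choices that matter, and what the synthetic
validation does and does not demonstrate about real data.

## 1. The problem

The scaphoid is the most frequently fractured carpal bone, and internal
fixation runs a screw through its narrow, curved body. Two population-level
descriptions support that intervention: a *statistical surface model* of the
bone's external form (osseous surface plus the four articular cartilage
facets for the radius, lunate, capitate and trapezium/trapezoid) and an
*averaged bone-density model* of its interior, from which candidate screw
pathways can be probed for the bone stock they would traverse. The package
implements both ends of this chain plus the synthetic cohort needed to test
them at desk scale.

## 2. The synthetic phantom family

No specimen scans ship with the package, so the cohort is simulated. A
phantom is a solid of revolution with an axial radius profile built from
four C1-joined arcs: an elliptical proximal cap rising to the proximal lobe
radius, a cosine blend down to the circular waist, a cosine blend up to the
distal lobe radius and an elliptical distal cap. The dorsal surface is
flattened by clamping the dorsal coordinate at half the `dorsal_width`
parameter, and the distal half is bent about the waist with a linear angle
ramp so the mesh stays continuous. Because the surface is analytic, the
homologous landmarks (pole tips, four waist extrema, two lobe-equator
points) and the four meridian segment polylines are placed *exactly* on
mesh lattice vertices — there is no landmarking error in the phantom world.

Generative parameters and their population spread (all drawn independently
per specimen, then deterministically clamped into the valid region):

| parameter | mean | SD | rationale |
|---|---|---|---|
| length | 26 mm | 5 mm | mean 2.6 cm with a ±2 SD range of 1.7–3.7 cm, the anatomical span |
| proximal / distal lobe radius | 6 / 7 mm | 0.6 mm | bone widths of 12–14 mm |
| waist radius | 5.2 mm | 0.5 mm | orthogonal waist diameters near 1 cm |
| waist axial position | 0.50 | 0.04 | waist translation toward the distal pole |
| dorsal width | 6.5 mm | 1.25 mm | dorsal strip widths of roughly 4–9 mm |
| bend angle | 15° | 4° | the scaphoid's flexed posture |

The density interior has three concentric zones assigned by depth below the
surface: a peripheral shell (thickness 1 mm, mean 549.4 mg HA/cm³), an
intermediate shell (thickness 2 mm) split into four subregions — outer
axial thirds along the long axis give the proximal-pole (379.0) and
distal-pole (346.5) subregions, and the angular halves of the middle third
about the second principal axis give medial (376.2) and lateral (389.1) —
and a trabecular centre (225.6). Zone means are population values reported
for the scaphoid; voxel noise is additive Gaussian (default SD
60 mg HA/cm³, clamped at 0), which reproduces means and SDs but *not* the
long min–max tails of real trabecular bone. Volumes are stored in HU with a
known linear calibration (slope 0.7, intercept 0) so the calibration path
is exercised end to end.

What the phantom does **not** emulate: trabecular microarchitecture,
cortical porosity, genuinely irregular articular facet boundaries,
landmarking error, and scanner artefacts. Passing the recovery tests
therefore shows the *pipeline machinery* is correct and well-conditioned on
bones of this scale and topology — not that segmentation or landmarking of
real HR-pQCT scans would be this accurate.

## 3. Preprocessing

Processing order is fixed: clamp attenuation below 0 HU to zero (defined in
HU, before calibration — the two operations commute only when the
calibration intercept is non-negative), mirror left specimens to right
(reflection across the object's sagittal mid-plane with triangle winding
re-flipped; for volumes the lattice maps onto itself so mirroring is an
exact involution), then apply `vBMD = a·HU + b`. Segmentation binarizes at
a threshold (default: midpoint between background 0 and the median of
above-zero voxels, since no fixed threshold is canonical), keeps the
largest 6-connected component, smooths the binary occupancy with a small
Gaussian (σ = 0.7 voxels) and contours it with marching tetrahedra at the
0.5 level. Smoothing before contouring matters: contouring raw binary data
puts every iso-crossing at a cell midpoint and inflates surface area by
tens of percent, while the smoothed occupancy recovers sub-voxel surface
positions (sphere area correct to ~2% at 0.25 mm voxels). Marching
tetrahedra (six-tetrahedra cube decomposition, face-consistent across
cells) guarantees a watertight, consistently outward-oriented surface, so
`T = 2V − 4` holds by construction and genus is a reliable diagnostic.

Nutrient foramina are closed automatically rather than manually:
voxelization at `max_hole_diameter/6`, morphological closing with a
Euclidean ball of radius `max_hole_diameter/2`, re-meshing. Channels wider
than the ball survive closing and are *reported* (warning plus an
`unclosed_genus` attribute), never silently altered. The `/6` voxelization
keeps the voxelize → close → re-mesh round trip volume-faithful (< 0.5%
on a hole-free sphere); a coarser `/4` grid was measured at ~0.9% drift.

## 4. Correspondence

Segment landmarks are resampled to equal counts at equal arc length along
their piecewise-linear polylines (endpoints preserved exactly), making the
full landmark sets row-wise comparable across specimens. The reference
specimen is chosen automatically as the one minimizing the summed pairwise
rigid-Procrustes distance of landmark configurations (overridable by
index). The reference mesh is warped to each target with an interpolating
3D thin-plate spline on the full landmark sets (kernel U(r) = r; λ = 0 by
default, with λ > 0 exposed for noisy landmarks) and each warped vertex is
projected to the nearest point on the target surface — the warp carries
anatomical identity, the projection guarantees the vertices lie on the
actual segmented surface. Projection ties across faces resolve to the
lowest face index, so correspondence is deterministic. Per-specimen mean
projection residuals are logged and specimens above half the reference's
mean edge length are flagged.

Numerics that proved necessary: the TPS system is solved in centred, scaled
coordinates with one step of iterative refinement, and kernel distances are
evaluated by direct differencing — the algebraically equivalent
`|p|² + |s|² − 2p·s` form loses about seven digits near control points and
would break the 10⁻⁸ mm interpolation property.

## 5. The statistical surface model

Alignment is a generalized Procrustes fit with translations and *proper*
rotations only: no scaling (centroid size is preserved exactly, so the PCA
analyses form = size + shape jointly) and no reflections (anatomical
chirality). Three numerical choices deviate from textbook minimal versions,
each forced by an invariant the package tests:

- the mean is initialized from the arithmetic mean of the centred shapes,
  not from the first specimen — initializing from a specimen re-rotates an
  already-aligned set into that specimen's frame and breaks idempotency;
- convergence is judged on the largest per-shape movement, not on the mean
  shape's movement — individual rotations can still drift while their
  average cancels;
- the tolerance default is 10⁻¹⁰ mm RMS, tight enough that re-aligning an
  aligned set moves vertices by less than 10⁻⁸ mm.

PCA is computed through the SVD of the N × 3V centred data matrix
(covariance divisor N − 1). Variance fractions are fractions of *total*
variance and sum to one over the N − 1 available modes. PCA signs are
arbitrary, so each mode is oriented to elongate the mean along its long
axis (second axis as fallback) — this fixes score signs across runs.
Shapes are synthesized as `mean + k·√λ·mode`.

Morphometrics: length is the extent along the first principal axis of the
vertex cloud. The waist is searched over 100 stations spanning the central
60% of the length as the smallest *interior local minimum* of cross-section
area; a profile without an interior narrowing (a sphere) falls back to the
mid-length station. Cross-section areas use the line integral of the
consistently oriented mesh-plane intersection segments, so multiply
connected sections are handled without polygon reconstruction. The two
waist diameters are the maximal in-plane point-pair extent and the extent
perpendicular to it. Dorsal width — whose measurement protocol is genuinely
underdetermined — is defined here as the mean, over nine stations along the
trimmed strip, of the bone-labelled strip's extent along the direction
perpendicular to both the long axis and the strip's mean normal. The
mean-model descriptors and the population statistics of per-specimen
descriptors are computed by distinct code paths and reported side by side;
on any size-varying population they differ (surface area is convex in
scale, so the single-model mean exceeds the mean-model value).

## 6. The averaged density model

An isotropic reference grid (default 0.3 mm here; 0.082 mm remains a
configuration choice for production-scale data) covers the mean shape's
bounding box; nodes are classified by ray-casting parity against the closed
mean mesh, with rays jittered off lattice planes to dodge degenerate
vertex/edge hits. For each specimen a TPS is fitted from a uniform
subsample of the mean's homologous vertices (default 500 controls at
production vertex counts, 300 at the test scale; fitting on all 50,000 is
numerically unnecessary — warp accuracy is already control-limited below
the grid spacing) to the specimen's corresponding vertices *in its native
volume frame* (the TPS affine part absorbs the rigid difference), every
inside node is warped and sampled trilinearly, and nodes are averaged over
specimens with per-node counts recorded.

Sampling is partial-volume aware: interpolation corners outside the
specimen's bone mask get zero weight and the remaining weights are
renormalized. Without this, nodes within one voxel of the surface blend
bone with background zeros and the peripheral shell would be biased low by
~10% — a masking technique standard in medical image resampling, adopted
here at design time for exactly that reason.

Zones are segmented on the grid by depth to the mean surface (defaults:
peripheral ≤ 1 mm, centre ≥ 3 mm, matching the generator's shell
thicknesses; these depths are configuration values, as no quantitative
boundary definition is canonical) with the same axial-thirds /
angular-halves subregion rule as the generator, sharing one implementation
so generator and model cannot drift apart. The deterministic axis-sign
convention (each principal axis oriented so its largest-magnitude component
is positive) keeps "medial" and "lateral" stable across runs. Zone volumes
are node counts times node volume, reported in mm³ — magnitudes reported
elsewhere under a cm³ header are consistent with mm³, and this package
sides with mm³ explicitly rather than matching an ambiguous unit.

**Known limitation (tested and documented rather than hidden).** With
identical specimens the averaged model recovers all six generating zone
means *exactly* (0.0% error), which pins the machinery down. Across a
size-varying population, however, the recovery of the thin centre zone
(depths 3–5 mm) is biased high by 5–10%: the generator places zone
boundaries at fixed absolute depths in every specimen, while a
surface-driven TPS maps interior points proportionally, so the mean-frame
centre zone receives intermediate-zone material from smaller specimens.
This is a real property of population averaging with absolute-depth zones,
grows with the anatomical size spread (length SD 5 mm here, matching the
reported 1.7–3.7 cm ±2 SD range), and vanishes as the spread shrinks. The
peripheral shell and all four intermediate subregions recover within 5%,
and the strict ordering peripheral > intermediate > centre always holds.

## 7. Virtual probing

A pathway is probed by sampling disks (centre + 3 rings × 8 spokes by
default) perpendicular to the path at 100 equally spaced stations and
averaging valid samples per station; `mode = "line"` ignores the diameter
for comparison with pure line probes, since it is not documented whether
the original tool disk-averages. Samples outside the volume or its tissue
mask are excluded; the profile and its path summary (mean/min/max over
stations) are returned. The default pathway pair on a mean model is a
central path along the long axis and a peripheral chord running just
beneath the flat dorsal surface (found by bisection on the dorsal offset
keeping the chord inside the mesh, minus a 0.5 mm margin). On noise-free
phantoms both agree with a direct voxel-masking oracle within 2%, and the
peripheral path's mean vBMD exceeds the central path's by a factor of
about 1.7.

## 8. Reproducibility and problem sizes

Every random draw in the pipeline derives from one global seed (per-stage
fixed offsets, so disabling a stage does not shift another's draws); runs
with identical config and seed produce byte-identical artifacts and
manifest hashes. The shipped analyses use a 43-specimen cohort at 0.3 mm
voxel and grid resolution with ~1,250-vertex test meshes (~2,000 for the
PCA recovery experiments) — sizes chosen so the full analysis completes in
about a minute on a laptop while every structural property being tested
(closedness, correspondence, conservation, recovery) is
resolution-independent. The unit and acceptance suites state their
tolerances next to each assertion; none of the numbers quoted in this
vignette are asserted anywhere without being recomputed by the tests or the
acceptance script.
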