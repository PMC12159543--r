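---
title: "Automated vessel wall/lumen morphometry: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated vessel wall/lumen morphometry: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The measurement problem

Arteriolosclerosis — hyaline thickening of small arterial and arteriolar
walls with narrowing of the lumen — is graded qualitatively in
neuropathology. Given a wall/lumen segmentation of a vessel sectioned
transversely, three quantities make the grading reproducible:

* the **sclerotic index** at angle $\theta$,
  $SI_\theta = 1 - D_i(\theta)/D_e(\theta)$, where $D_i$ and $D_e$ are the
  internal (lumen) and external (outer wall) diameters through the lumen
  centroid, evaluated at each degree over a half circle (the diameter at
  $\theta$ and the diameter at $\theta + 180^\circ$ are the same line);
* the **wall thickness**, estimated two ways: the *tangent-line* method
  measures, at 100 arc-length-equidistant points on the lumen contour, the
  distance from the contour point along the outward normal (perpendicular to
  the local tangent) to the external contour, $T_\alpha = E - L_\alpha$;
  the *radii* method measures $T_\theta = R_e(\theta) - R_i(\theta)$ along
  rays from the lumen centroid at each degree of a full circle;
* the **wall-to-lumen area ratio**: pixel counts of the two masks scaled by
  the squared resolution (at 0.220 μm/px, 0.0484 μm² per pixel) and divided.

Each measurement set is summarized by median, mean, sample standard
deviation (n−1 denominator; a single measurement reports sd 0), minimum,
maximum, and the number of contributing measurements. Excluded or invalid
measurements never enter the statistics; they are counted in the report's QC
block instead.

The package also implements the tile machinery these measurements sit in:
conversion of pixel-wise segmentations into tile confidence scores (mean
vessel probability over pixels where the vessel class strictly dominates,
zero when no pixel qualifies), recursive centering of tiles onto detected
vessels (ORCA), and a gridded end-to-end pipeline. Trained neural networks
are deliberately out of scope; segmenters and classifiers are pluggable
function contracts, and classical reference implementations (intensity
threshold, hole fill, small-component removal; a logistic in the area ratio)
stand behind them so the geometry is testable end to end.

## Ray casting and the boundary convention

All radial quantities are measured by casting rays and locating region
transitions. Binary masks are treated as continuous indicator fields via
bilinear interpolation, with region membership defined by the 0.5 level —
the same sub-pixel boundary that `contourLines()` traces. Rays are sampled
every 0.25 px; a transition is placed at the midpoint between the two
samples that bracket it, so the locational quantization is ±0.125 px.
Per design:

* $R_i$ (and $D_i$) use the **first** lumen→non-lumen transition, which is
  conservative for involuted lumens;
* $R_e$ (and $D_e$) use the **last** wall→background transition, spanning
  the full vessel externally;
* an angle is **invalid** when a ray meets background before wall after
  leaving the lumen (a broken wall ring), or when the ray leaves the raster
  before exiting the wall; if the lumen centroid falls outside the lumen
  (extreme involution), the whole profile is invalid and flagged in QC.

On rasterized circle phantoms this estimator recovers $R - r$ with a mean
error below 0.1 px. The residual per-angle scatter is dominated by the
raster itself: a binary mask of a radius-10 circle carries ±0.5 px of
boundary wiggle, which bounds any estimator's worst-angle sclerotic-index
deviation near 0.026. Mean statistics over 180 or 360 angles average this
noise down an order of magnitude, which is why accuracy claims here are
stated on profile means.

## The tangent-line estimator

The lumen contour is extracted at the 0.5 level, oriented counterclockwise,
and resampled to 100 arc-length-equidistant points starting at the point
with the smallest positive angle from the centroid's +col axis (ties broken
by index) so the sampling is deterministic. Tangents are estimated by
central differences over a moving-average-smoothed window of half-width 4
contour points. A half-width of 2 leaves enough normal-direction noise from
the contour's raster zigzag to move individual thickness measurements by
up to ~0.8 px on eccentric phantoms; half-width 4 brings per-point
agreement with a fine-step ray-marching oracle under 0.7 px while remaining
narrow relative to the ~100-point contour. Contact points are never
smoothed — only the tangent direction uses the smoothed curve.

Two exclusion rules apply, and excluded points are reported with reasons:

* `inward_pointing`: the outward normal satisfies
  $\mathbf{n} \cdot (\mathbf{p} - \mathbf{c}) < 0$ for lumen centroid
  $\mathbf{c}$ — the measurement line would cross the lumen, as happens
  inside lumen involutions;
* `no_intersection`: the ray leaves the raster before exiting the wall.

## Phantoms: what they emulate and what they do not

`phantom_spec()` + `render_phantom()` generate cross-sectioned vessels with
analytic ground truth: circular, elliptical, involuted, or spiked lumens
inside circular/elliptical outer walls, optionally eccentric (offset)
lumens, three gray levels (eosin-dark wall 90, near-white lumen 240, pale
background 200 by default), and seeded additive Gaussian noise clipped to
[0, 255]. Rasterization uses the pixel-center rule — a pixel belongs to a
region iff its center satisfies the region inequality — which makes simple
pixel-counting the area oracle. Truth masks are noise-free, and identical
spec + seed gives bit-identical output without disturbing the caller's RNG
stream.

Two involution shapes are provided because they probe different failure
modes. The polar notch
$r(\phi) = r\,(1 - d\,\max(0, \cos k\phi)^4)$ dents the contour inward with
a single knob, but the curve remains star-shaped around its center, so its
outward normals *never* point towards the lumen center — at any depth
$d < 1$, analytically and in practice. Reproducing the pathological case
where measurement lines cross the lumen requires a non-star-shaped contour;
`shape_spiked()` (a thin wall spike protruding from the boundary past the
lumen center) produces it deterministically, and is the fixture used to
exercise the `inward_pointing` exclusion.

Phantoms emulate geometry and intensity contrast only. They do not emulate
H&E color, stain variability beyond Gaussian noise, nuclei or corpora
amylacea confusers, or annotation noise — so passing phantom tests
demonstrates the correctness of the geometry and score computations, not
segmentation performance on real tissue.

## Why the two thickness estimators differ on eccentric vessels

For a circular lumen the outward contour normal is exactly the radial
direction from the lumen center, so the tangent-line and radii methods
measure along the same rays and agree to within discretization noise —
*even when the lumen is offset inside the wall*. A genuine, robust ordering
(radii mean ≥ tangent mean) appears for elongated vessels: from an interior
point, the radial chord to the outer boundary is the shortest chord, and on
the flanks of an elongated section the centroid ray crosses the wall
obliquely while the tangent-line ray stays near the wall normal. This
obliquity — amplified by irregular lumen contours in real vessels — is the
mechanism behind the large radii-vs-tangent gap seen on real
arteriolosclerotic vessels. The eccentric-ordering checks therefore use
shifted *elongated elliptical* lumens (offset ≥ 3 px, axis ratio ≈ 3),
where the ordering margin is a stable 1–1.8 px, rather than offset circles,
where the two estimators tie by construction.

## ORCA

`orca_center()` repeats extract → segment → binarize → target → re-extract,
with the new tile origin placed so the target sits at the tile center,
clamped to the source bounds (never padded, preserving native pixels).
The centering target is the centroid of the largest 8-connected detected
component — deterministic on multi-vessel tiles — with a union-centroid
mode for vessel clusters that should be centered as a group. Convergence is
declared when the Euclidean origin shift drops below `shift_threshold`
(default 8 px, ~1.5% of a 512 tile width; configurable), with a `max_iter`
cap of 10. With an exact segmenter, a vessel fully visible in the seed tile
converges in at most two iterations (the second merely confirms a zero
shift); a vessel partially cropped by the seed tile needs one extra
iteration, because the centroid of the visible fragment is biased; a vessel
entirely outside the seed tile terminates immediately with reason
`"empty detection"` — centering cannot create information the first tile
does not contain.

## Pipeline defaults and degenerate inputs

The pipeline tiles from origin (0,0) with non-overlapping stride equal to
the tile size, dropping partial edge tiles (logged). Detection keeps tiles
with confidence ≥ 0.5; the reference classifier gates at score 0.5 around a
configurable ratio midpoint (default 2). Tiles that converge onto an
already-reported vessel (final origins within the shift threshold) are
dropped as duplicates, so each vessel is reported once even when it
straddles a tile boundary. Validation requires exactly one 8-connected
wall∪lumen component *and* exactly one lumen component — vessels with
contiguous walls form a single component but carry several lumens, and are
rejected as `"multi-vessel tile"` rather than measured incorrectly — and a
closed wall ring (no 4-connected path from lumen to border through
non-wall pixels). Empty lumens yield areas with an undefined (NA) ratio and
score 1 from the classifier (fully stenosed convention). Binarization ties
at a 2-class probability of exactly 0.5 go to background; 3-class argmax
ties resolve towards the lower class index.

The eccentric-sectioning correction (`eccentricity_correction()`: a section
at angle $\theta$ yields $d_s/d_l = \cos\theta$, correction factor
$1/\cos\theta$) is computed and reported but never applied inside default
reports.

## Problem sizes and reproducibility

The shipped checks use 20 seeded concentric-circle phantoms on 160-px
canvases (lumen radius 8–40 px, wall margin 4–16 px, capped at 60 px), five
shifted elongated ellipses on 180-px canvases, one 2048-px synthetic slide
for ORCA, 64-px masks and 100 scores for the metric oracles, and 1024-px
three-vessel slides with 256-px tiles for the pipeline — sizes at which
every oracle can be enumerated exactly and the full suite runs in well
under a minute. All randomness flows from explicit seeds through
`withr::with_seed()`, so runs are bit-reproducible.

## Known limitations

* Single-vessel morphometry only: contiguous-wall clusters are detected and
  rejected, not split.
* The sclerotic index averages per-angle values (a best-fit diameter pair is
  not implemented); with elliptical lumens the per-angle mean differs from
  any single-pair definition.
* The eccentricity correction is reported, never applied.
* Phantom realism is geometric; no claims transfer to stained tissue
  without a real segmenter behind the contract.
* Hausdorff is the classic symmetric max–min on boundary pixels; no
  percentile variant is provided.
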