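---
title: "Methods: from TOF-MRA volume to projected facial arteries"
author: "arterymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from TOF-MRA volume to projected facial arteries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate conventions

All world coordinates are right–anterior–superior (RAS) millimetres; DICOM's
LPS frame is converted on read by negating the first two axes. Voxel indices
are 1-based in R (the command-line `--axis` flag is 0-based, matching common
imaging tools), and the voxel *centre* carries the world coordinate:
`world = origin + orientation %*% (spacing * (index - 1))`. 4-D inputs are
rejected rather than squeezed — the pipeline is defined on single-echo 3-D
volumes, and silent squeezing hides acquisition mistakes.

## Vessel enhancement

Arteries in TOF-MRA are bright tubes on a suppressed-tissue background. The
enhancement stage computes, per scale $s$, Gaussian-derivative Hessians with
physical-space standard deviation $s$ on every axis (anisotropic spacing is
honoured by per-axis kernel sampling; truncation at $4\sigma$; reflect
boundary, which avoids the spurious edge responses of zero padding). Sampled
derivative kernels are moment-corrected so that first and second derivatives
of linear and quadratic signals are reproduced exactly — this makes the
small-volume analytic tests sharp and costs nothing. The Hessian is
multiplied by $s^2$ ($\gamma = 2$ normalization) so responses are comparable
across scales, and its eigenvalues $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$
are obtained from a vectorized closed-form symmetric $3\times 3$ solver with
a Newton polish (validated against LAPACK to $10^{-8}$ in the tests).

The response at one scale, for bright structures (eigenvalues sign-flipped),
uses the regularized eigenvalue
$\lambda_\rho = \lambda_3$ if $\lambda_3 > \tau \max_x \lambda_3$,
$\tau \max_x \lambda_3$ if $0 < \lambda_3 \le \tau\max_x\lambda_3$, else $0$:

$$V \;=\; \lambda_2^2\,(\lambda_\rho - \lambda_2)\,
  \left(\frac{3}{\lambda_2 + \lambda_\rho}\right)^3,$$

set to $0$ where $\lambda_2 \le 0$ or $\lambda_\rho \le 0$ and clamped to
$1$ where $\lambda_2 \ge \lambda_\rho/2 > 0$ (the formula itself equals 1 at
that boundary, so the response is continuous). The multiscale response is
the pointwise maximum over scales; $\max_x \lambda_3$ is taken per scale
over the whole volume.

Three parameter choices matter:

* **Scales** default to $\{0.5, 0.75, 1.0, 1.5, 2.0\}$ mm — facial-artery
  radii are roughly 0.5–1.5 mm, and the response of a Gaussian tube peaks at
  a scale within a factor two of its radius.
* **$\tau = 0.5$**, the sensitive low end of the usual range; it favours
  thin, low-contrast vessels at the cost of more background response.
* **Numerical noise floor.** The response formula is deliberately
  contrast-invariant, which means that on a *constant* volume the
  $10^{-16}$-level rounding residue of the filters would be enhanced like
  real structure. Eigenvalue fields therefore carry a floor of
  $10^{-10}\times\max|I|$ below which the per-scale maximum is treated as
  zero. This leaves any realistic contrast untouched (it sits ten orders of
  magnitude below tissue contrast) and makes constant volumes map to
  exactly zero.

## Segmentation and the subcutaneous band

Segmentation is a plain threshold on the normalized response (default 0.5;
`"auto"` uses Otsu's histogram threshold). The *separation* step restricts
the vessel mask to the subcutaneous band: the head is the largest
26-connected component above an automatic intensity threshold, closed with
a 2 mm ball (morphology implemented via the exact spacing-aware Euclidean
distance transform) and hole-filled; the band keeps head voxels whose
distance to the outside is at most `band_depth_mm` (default 15 mm — "between
skin and skull" is anatomy, not a number, and 15 mm covers the subcutaneous
course of the facial arteries) and, in the pipeline defaults, more than
`skin_margin_mm = 2.5` mm. The margin excludes the cutis itself: no
*sub*cutaneous artery runs in the outermost 2–3 mm, and the air–skin
boundary is the one place where a curved bright edge can locally imitate a
tube at the largest scale. The bare `subcutaneous_band_mask()` contract
(margin 0) is unchanged; the margin is a composition choice of the pipeline.

Components smaller than 20 voxels (26-connectivity) are removed — at
0.5 mm isotropic sampling that is a vessel fragment shorter than ~2 mm,
below anything the labeling or evaluation stages can use.

## Meshing

The arterial surface is extracted by marching cubes on the binary mask at
iso-level 0.5, after padding by one background voxel so every surface
closes. The 256-case triangulation table is generated programmatically at
load time: per cube face, marching-squares crossing segments (ambiguous
diagonal faces resolved by a fixed rule applied identically on both sides of
a shared face, so neighbouring cubes always stitch), traced into closed
loops and fan-triangulated about the loop centroid. Because the field is
binary, crossings sit at edge midpoints and the geometry per configuration
is fixed.

Midpoint marching cubes on binary data systematically overestimates curved
surface areas (the staircase bias is ~9% on a 8 mm ball at 0.5 mm spacing),
so the mesh is post-processed with Taubin smoothing (default 10
shrink/inflate iterations, $\lambda = 0.5$, $\mu = 0.53$) followed by a
per-component uniform rescale about the component centroid that restores the
enclosed volume of the raw mesh. This brings the ball's area within ~2% of
analytic while keeping single-voxel components at their correct enclosed
volume — the same role smoothing filters play in the standard ITK/VTK
meshing pipelines. `smooth_iterations = 0` returns the raw surface.

## Centerlines

Centerlines come from topology-preserving directional thinning (six
subiterations per pass; a border voxel is deleted only if it is a simple
point — one 26-component of foreground in its 26-neighbourhood, one
6-component of background in its 18-neighbourhood — and not a curve
endpoint). The skeleton graph is decomposed at junctions (degree ≥ 3),
branches shorter than `min_branch_mm` (default 5 mm) are pruned, and each
branch is reported as an ordered polyline in mm with per-point radii from
the distance transform. Tie-breaks and traversal order are lexicographic in
voxel coordinates, so output is reproducible and independent of input
order. A compact blob (no elongation) legitimately thins to branches below
the pruning length and yields an empty list.

## Anatomy labeling

The study identified arteries by expert comparison with maximum-intensity
projections; this package substitutes a deterministic, reproducible
heuristic and always permits `unclassified`. From a 68-point landmark set
(iBUG-style indexing: 17 jaw, 10 brow, 9 nose, 12 eyes, 20 mouth) it builds
one spherical region per artery and side, anchored on named landmarks
(mid-jaw/mouth-corner corridor for Fa, labial bands for IL/SL, nose-wing
flank for Ang/LN, nasal dorsum for DN, medial/central brow for STr/SO, a
temporal box lateral to the eye for ST). All sizes scale with the outer
inter-ocular distance, centres are pulled 0.10 of that distance towards the
face centroid (arteries run a few mm below the landmark surface), and the
right side is the exact mirror image of the left across the midsagittal
plane fitted through the nine midline landmarks (28–31, 34, 52, 58, 63,
67). Mirror construction makes the left/right symmetry an invariant rather
than a property of symmetric inputs. Region geometry is calibration data in
`inst/extdata/region_atlas.json`, versioned with the package.

A polyline takes the label whose region contains the largest fraction of
its points if that fraction reaches 0.5; ties break by centroid distance,
then fixed label order.

## Registration and projection

Model-to-subject matching uses a 7-parameter similarity transform (faces
are rigid at this scale; an affine alternative was deliberately not made the
default because shear has no anatomical meaning here). The closed-form
least-squares solution (centroid alignment, SVD of the cross-covariance with
a reflection guard that flips the smallest singular axis if the raw optimum
is a reflection, scale from the variance ratio) minimizes
$\sum_i \|sRx_i + t - y_i\|^2$. The reported `rms_mm` is the per-coordinate
root-mean-square residual, which converges to the landmark noise SD for
isotropic Gaussian noise. Degenerate (collinear/coincident) sources are
refused.

The camera is an undistorted pinhole: $u = f_x X/Z + c_x$,
$v = f_y Y/Z + c_y$ after the world-to-camera pose; points not strictly in
front of the camera are an error, not a NaN. Pose from 2-D landmarks is
estimated by Gauss–Newton (Levenberg damping on rejection) on the
reprojection residuals, with a deterministic initialization: back-project
the 2-D landmarks at a nominal 500 mm depth, similarity-fit the model to
those points, keep rotation and translation. Iteration stops when the step
norm falls below $10^{-10}$ — also when such a step no longer improves the
cost, which is the stationarity signature under noisy landmarks; a
genuinely non-converged state raises an error carrying the last residual.
Depth is observable here (68 non-coplanar points, known intrinsics), so no
scale ambiguity arises.

## Accuracy statistics

Deviation records are tidy tibbles (`patient`, `side`, `artery`,
`visualized`, `deviation_mm`). Group statistics use the sample SD (n − 1),
with single-member groups reporting SD 0. The *overall* mean and SD are the
unweighted means of the 18 per-group means and SDs — this is the
aggregation consistent with the published summary row (the per-record
pooled alternative, which differs, is available via `aggregate =
"pooled"`). Blank cells and em-dashes in the wide input table both mean
"not visualized" (exactly one blank exists in the packaged table, patient
13's right angular artery, consistent with that group's published n = 18).
Printed-precision comparisons round half-up (0.625 → 0.63), matching the
source tables rather than IEEE round-half-even.

The brace recomputation assumes every artifacted labial artery belongs to a
brace-wearing patient, so only the denominator changes:
$2\,(n_\text{subjects} - n_\text{excluded})$.

On-face deviation against a projected curve is the nearest-point distance
(point-to-segment, not sampled-vertex), converted by an isotropic
pixel-to-mm factor. Perpendicular distance to an idealized straight artery
would differ only in curvature regions; nearest-point is the declared
convention because it is well-defined for any curve shape.

## The synthetic phantom

The generator emulates bright-blood TOF contrast: an ellipsoid "head" of
tissue intensity 100 on background 0, vessels as tubes of Gaussian
cross-section with $\sigma = r/2$ (differentiable intensity suits Hessian
filtering and mimics partial-volume blur) and peak 200 above tissue, and
seeded Gaussian noise with $\sigma$ = 5% of peak (a Rician magnitude option
exists, since TOF magnitudes are Rician). The default grid is $160^3$ at
0.5 mm — that size matters beyond runtime: the skin is a curved bright edge,
and its tangential Hessian response at scale $s$ grows with curvature as
$\approx s\,\Delta\,\kappa/\sqrt{2\pi}$. A head much smaller than ~35 mm
semi-axis (a half-scale head) is curved enough for the skin shell to cross
the 0.5 response threshold at the 2 mm scale — a modelling artifact, not a
property of patient-scale anatomy. The standing phantom conditions
therefore use 32–38 mm semi-axes, vessels ~3.5 mm deep (region-anchored
arcs via `default_phantom_vessels()`), and the canonical single-tube
benchmark (`single_tube_spec()`) plants a radius-1 mm tube 12 mm below the
skin, entirely inside the default band.

Landmarks sit at fixed azimuth/elevation constants on the head surface, so
bilateral pairs mirror exactly and scaling the head scales all pairwise
distances exactly; rendered views are exact pinhole projections plus seeded
pixel noise. Every generator output is a pure function of spec + seed (the
session RNG state is saved and restored).

What passing phantom tests do **not** show about real data: no flow
saturation or slab-boundary artifacts, no dental-metal artifacts (their
effect is represented simply by absent labial vessels), no soft-tissue
intensity texture, a rigid analytic head rather than an articulated face,
and landmark noise that is i.i.d. Gaussian rather than tracker-structured.

## Problem sizes and budgets

Unit tests run on 6³–48³ volumes; the end-to-end recovery checks run the
full chain twice on 160³ phantoms (roughly a minute each), chosen as the
smallest grid at which head curvature is realistic (see above). The
acceptance script repeats those two chains plus 100 seeded similarity
recoveries.

## Known limitations

* Threshold-based segmentation has no notion of vessel connectivity; very
  low-contrast vessel segments fragment rather than degrade gracefully.
* The region atlas is a geometric stand-in for expert identification; it
  cannot distinguish arteries whose courses genuinely overlap a region
  (angular vs. lateral nasal in some anatomies), and its calibration has no
  clinically validated provenance.
* Projection is depth-free; overlays are evaluated in the image plane only.
* DICOM reading supports uncompressed explicit-VR little-endian single-frame
  series — the common interchange case — not compressed or multi-frame
  syntaxes.
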