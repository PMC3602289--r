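---
title: "Fusing prone MRI, standing X-ray and surface topography into one torso model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing prone MRI, standing X-ray and surface topography into one torso model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsofuse)
```

## The registration problem

Pre-surgical imaging of adolescent idiopathic scoliosis typically produces
three complementary and mutually misaligned views of the same trunk:

* axial **MRI** slices, acquired with the patient lying **prone**, carrying
  soft-tissue information;
* a 3D **spine reconstruction from biplanar X-rays**, acquired **standing**,
  giving per-vertebra landmark sets;
* a **surface topography (TP)** scan — an optical structured-light mesh of
  the external torso, also acquired **standing**, with adhesive external
  markers (radio-opaque duplicates are visible on the X-rays).

Between the prone and standing acquisitions the spine changes shape and the
soft tissue deforms, so no single rigid transform aligns the modalities. The
deformation is a mixture: vertebrae are rigid bodies and must stay rigid,
while the tissue between spine and skin deforms smoothly. `torsofuse`
implements a registration pipeline that honors exactly that split.

## The model

**TP to X-ray.** The external markers give true point correspondences, so a
3D thin-plate spline (TPS) is fitted on the marker pairs and applied to every
TP mesh vertex. The TPS is the Bookstein form
\(f(p) = a_1 + a_2 x + a_3 y + a_4 z + \sum_i w_i U(\lVert p - p_i \rVert)\)
with the 3D kernel \(U(r) = |r|\), one coefficient set per output
coordinate, solved from the block system
\([K + \lambda I,\ P;\ P^\top,\ 0]\,[w; a] = [V; 0]\). The side condition
\(P^\top w = 0\) removes affine leakage into the kernel term. With
\(\lambda = 0\) the fit interpolates the markers exactly.

**Articulated bone alignment.** MRI and X-ray vertebral landmarks differ in
kind (8 body-edge points vs 6 endplate/pedicle points), so no cross-modality
point correspondences exist. Instead each vertebra gets a local coordinate
frame — centroid plus an orthonormal lateral/anterior/superior triad
estimated from the landmark roles — and the spine becomes a chain of rigid
intervertebral transforms. Global per-vertebra transforms fold the chain,
\(T_{0,v} = T_{v-1,v} \circ \dots \circ T_{1,2} \circ T_{0,1}\), and the
per-vertebra cross-modality bone transform is
\(T_{v\text{-bone}} = T_{0,v}^{Xray} \circ (T_{0,v}^{MRI})^{-1}\).
Each axial slice is assigned to the vertebra with the nearest z (ties go
inferior; the slice z is taken at its mask centroid mapped to world, so the
rule survives arbitrary poses) and is resliced pose-only: pixels are never
resampled in this step, so in-plane geometry is exactly preserved.

**Soft-tissue refinement.** After bone alignment the slice plane is cut
through the registered TP mesh. Rays from the vertebra center at fixed
angular steps (default 30°, i.e. 12 rays; angle 0 along the vertebra's
anterior direction) pair the outermost crossing of the MRI torso contour
with that of the TP cut. These pairs drive an in-plane *edge TPS* (same
\(|r|\) kernel with a 2D affine part, which keeps the planar system
well-posed). The final per-point map blends that TPS with the identity:

\[
T(p) = \begin{cases} p, & p \text{ inside the vertebra},\\
p + \rho(p)\,\bigl(T_{edge}(p) - p\bigr), &
\rho(p) = \dfrac{D_{vertebra}(p)}{D_{surface}(p) + D_{vertebra}(p)},
\end{cases}
\]

where \(D_{vertebra}\) and \(D_{surface}\) are Euclidean distances to the
vertebra border and to the torso border. \(\rho\) is 0 on the vertebra
border and 1 on the skin, so the vertebra stays rigid, the torso contour
lands exactly on the TP cut (for \(\lambda = 0\)), and the deformation
grades continuously in between. A literal reading of a "scalar times
transform" weighting is ill-typed; the identity-blended displacement above
is the unique interpretation that reproduces all three limit behaviors, and
it is what the package implements.

**Validation.** Per-slice overlap between the registered torso mask and the
TP cut interior is scored with the Dice coefficient
\(2|A \cap B| / (|A| + |B|)\) (a denominator written as a union would make
self-overlap 2, not 1, so the standard form is used). A volumetric variant
rebuilds a surface over the registered contour stack (ring stitching plus
one 1-to-4 linear subdivision), voxelizes it at 1×1×3 mm, and compares
volumes voxel-wise. Deformation quality is mapped with the determinant of
the Jacobian of \(x \mapsto x + u(x)\), with partials estimated by
first-order Gaussian-derivative filters (\(\sigma = 1\) px); det = 1 means
local volume preservation, and the rigidity constraint forces det = 1 inside
vertebrae. We adopt the standard convention that det > 1 is local expansion.

## The phantom

No public torso MRI/X-ray/TP triplet exists, so the package ships a phantom
generator whose outputs play the role of patient data with known ground
truth:

* **Spine**: 17 thoracic and lumbar vertebrae (T1–T12, L1–L5) at 24 mm
  spacing (~400 mm trunk — with 12 mm axial spacing that yields ~33 slices),
  centers on a laterally bowed line (Gaussian bump, width 60 mm) with
  coupled axial rotation. The default study curve is set by inverting the
  amplitude–angle relation for a 50° Cobb-like angle at apex T9 — the
  severity of a typical surgical candidate. Each vertebra carries the 6
  X-ray and 8 MRI landmarks as rigid-body copies of centroid-centered
  templates, so frames recovered from either set agree exactly.
* **Prone deformation**: each intervertebral joint is perturbed by rotations
  drawn uniformly within ±3° per axis and translations within ±2 mm —
  chosen once as a plausible magnitude for postural change; no measured
  bounds exist for these perturbations, so they are study conditions, not
  calibration targets. The exact per-joint offsets are recorded; folding
  them back reproduces the standing spine to < 1e-9 mm (a closure test).
* **Torso**: elliptical cross-sections (140 × 100 mm semi-axes, center
  40 mm anterior of the spine) following the lateral curve; lying prone
  compresses the anterior half radially by factor 0.85. Markers are snapped
  to exact mesh vertices at their anatomical roles.
* **Slices**: analytic masks rasterized at 1×1 mm with pixel-center
  convention, vertebra bodies as filled ellipses (no posterior elements —
  only the body drives the frames).

What the phantom does *not* emulate: MRI intensities (only geometry and
masks are needed), ribs/scapulae/pelvis, breast tissue, gravity, and
tissue-specific elasticity. Passing tests therefore demonstrate geometric
correctness of the method, not anatomical fidelity on real patients.

## Numerical choices

* Transform composition `compose_rigid(t2, t1)` applies `t1` first —
  matching right-to-left chain notation; unit tests pin this down, since it
  is the main ambiguity surface of articulated models.
* Rotations are stored as matrices; Euler angles only for reporting.
* TPS solver: dense solve with one iterative-refinement step, a
  condition-number error above 1e12 and a warning above 1e10; degenerate
  (coplanar/collinear) control points are rejected before solving. Kernel
  distances at evaluation are formed per control point (the expanded
  dot-product form cancels catastrophically near control points).
* The \(|r|\) kernel is conditionally negative definite, so the smoothing
  term is applied on the sign-consistent system (\(-K + \lambda I\), weights
  negated back): identical to the plain system at \(\lambda = 0\), but
  monotone and resonance-free for \(\lambda > 0\).
* The marker TPS defaults to \(\lambda = 0\) (true correspondences); the
  edge TPS defaults to \(\lambda = 10^{-3}\) (contour samples are
  correspondences by construction, not anatomy, so a slightly approximating
  fit is appropriate). The distance maps are computed on the
  articulated-transformed slice grid, i.e. after bone alignment and before
  soft-tissue blending.
* Distance maps use an exact Euclidean distance transform with the border
  defined as mask pixels 4-adjacent to the complement, making the distance
  exactly zero on the border — which pins \(\rho\) to 0 and 1 at its two
  anchors.
* Gaussian-derivative kernels are truncated at radius \(\lceil 3\sigma
  \rceil\) and normalized to unit response on a linear ramp, so a uniform
  scale field yields its exact analytic determinant and the field is
  identically 1 deeper than \(3\sigma\) inside vertebrae.
* Voxelization casts vertical rays per voxel column with parity counting;
  duplicate edge crossings are collapsed. Ray correspondences take the
  outermost contour crossing (torso slices are near-convex; multiple
  crossings are a logged rarity).
* Ties in slice-to-vertebra assignment go to the inferior vertebra — a
  declared convention, as no rule is implied by the data.

## Scale of the shipped experiments

The test suite exercises coarse (2–4 mm in-plane) phantoms for module tests
and one full-resolution study (17 vertebrae, ~33 slices at 1×1 mm, all
three methods, volumetric Dice) chosen to keep a complete run comfortably
on a single CPU. The same full-resolution study backs the acceptance
script. These sizes are the package's chosen experimental conditions; the
generators accept larger ones.

## Known limitations

* Correspondences between MRI contour and TP cut are directional samples,
  not anatomical landmarks; their accuracy is bounded by the near-convexity
  of the torso.
* The 2D Dice assumes slice orientation is already correct after bone
  alignment (the volumetric Dice removes part of that bias).
* Overlap metrics do not measure anatomical correctness of the interior
  deformation; the phantom's known ground truth mitigates this only for
  synthetic data.
* The rigid baseline is a declared comparator (least-squares frame fit over
  all vertebrae); other rigid choices would shift baseline numbers.
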