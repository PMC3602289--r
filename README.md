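# torsofuse

Multimodal registration of the scoliotic torso: fuse **prone-position axial
MRI slices**, a **standing-position biplanar X-ray spine reconstruction**,
and a **standing-position surface topography (TP) scan** into a single 3D
patient model that keeps vertebrae rigid and confines soft tissue to the
volume between spine and skin.

The package is aimed at researchers building trunk models for scoliosis
surgical planning and at anyone who needs its parts: 3D/2D thin-plate-spline
landmark registration with the `U(r) = |r|` kernel, articulated spine models
from per-vertebra coordinate frames, rigidity-constrained per-slice
deformation, mask/mesh/voxel Dice validation, and Jacobian-determinant maps
of deformation fields. Because no public MRI/X-ray/TP patient triplet
exists, a first-class phantom module generates complete synthetic datasets
with known ground-truth prone-to-standing deformation.

## Method at a glance

1. **TP → X-ray** (`register_tp_to_xray`): thin-plate spline
   `f(p) = a₁ + a₂x + a₃y + a₄z + Σᵢ wᵢ U(‖p − pᵢ‖)` fitted on paired
   external markers, solved from `[K + λI, P; Pᵀ, 0][w; a] = [V; 0]`.
2. **Bone alignment** (`build_articulated`, `cross_modality_transforms`):
   per-vertebra frames from landmark sets; intervertebral rigid chains
   `T₀,ᵥ = Tᵥ₋₁,ᵥ ∘ … ∘ T₀,₁`; per-vertebra bone transform
   `Tᵥ = T₀,ᵥ(Xray) ∘ T₀,ᵥ(MRI)⁻¹` applied pose-only to each axial slice.
3. **Soft tissue** (`register_slice`): the TP mesh is cut at the resliced
   plane; rays every 30° from the vertebra center pair the MRI torso contour
   with the TP cut; an in-plane edge TPS is blended with the identity by
   `ρ = D_vertebra / (D_surface + D_vertebra)` so the map is identity inside
   vertebrae and lands the skin on the TP cut.
4. **Validation** (`dice_2d`, `build_torso_mesh`, `voxelize`, `dice_3d`,
   `jacobian_determinant`, `compare_methods`): per-slice Dice
   `2|A∩B|/(|A|+|B|)`, volumetric Dice at 1×1×3 mm, and Gaussian-derivative
   (σ = 1) Jacobian-determinant maps whose value is 1 inside vertebrae.

## Worked example

```r
library(torsofuse)

res <- run_pipeline(pipeline_config(seed = 7))
print(res)
#> pipeline_result
#> method_comparison (wilcoxon paired test)
#>       method      mean          sd  n
#>        rigid 0.9401561 0.018223441 33
#>  articulated 0.9315170 0.014774676 33
#>     proposed 0.9928102 0.003183871 33
#> best by mean Dice: proposed
res$comparison$p_values["proposed", "articulated"]
#> [1] 5.644724e-07
```

The phantom here has a ~50° right thoracic curve, per-joint prone
perturbations up to 3°/2 mm and 0.85 anterior prone compression. The three
rows are mean ± SD per-slice Dice overlap between each method's registered
torso masks and the TP planar cuts over all 33 axial slices: the global
rigid fit and the articulated (bone-only) transform leave the prone tissue
compression uncorrected (Dice ≈ 0.93–0.94), while the proposed weighted-TPS
refinement fits the torso into the surface topography (Dice ≈ 0.99); the
paired Wilcoxon p-value shows the improvement is consistent across slices.

Single pieces work standalone, e.g.:

```r
spine <- generate_spine(list(amplitude = amplitude_for_cobb(50),
                             apex = "T9", axial_rot = 15),
                        posture = "prone", seed = 1)
cobb_angle(spine)        # ~50 (deg)
```

A thin CLI wrapper ships in `inst/cli/torsofuse`
(`torsofuse simulate|run --config cfg.yaml --out DIR --seed N`).

## Layout

| path | contents |
| --- | --- |
| `R/` | phantom, geometry, TPS, articulated model, soft tissue, validation, I/O, pipeline |
| `tests/testthat/` | unit, property and acceptance tests |
| `scripts/acceptance.R` | recompute headline quantities |
| `vignettes/torsofuse-methods.Rmd` | model, assumptions, parameter rationale, limitations |
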