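Package: torsofuse
Title: Multimodal Registration of the Scoliotic Torso
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses torso MRI slice stacks acquired in prone position with
    standing-position biplanar X-ray spine reconstructions and surface
    topography scans into a single 3D patient model. Bone alignment uses an
    articulated spine model built from per-vertebra coordinate frames and
    intervertebral rigid transforms; soft tissue is deformed with a
    distance-weighted thin-plate spline that is constrained to the identity
    inside vertebrae. Includes a synthetic scoliotic-torso phantom generator
    with known ground-truth prone-to-standing deformation, and validation
    tools: per-slice and volumetric Dice overlap, contour-stack surface
    meshing, anisotropic voxelization, and Jacobian-determinant maps of the
    deformation field.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
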