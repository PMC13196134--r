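Package: halluxrom
Title: Osteological Range of Motion, Moment Arms and Muscle Architecture
    of Hallucal Grasping Joints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collision-based mapping of the osteological range of motion at a
    two-bone joint (entocuneiform-first metatarsal), cosine-corrected Euler
    pose-space volumetrics via 3D alpha shapes, per-pose instantaneous muscle
    moment arms about the joint's center of rotation, metatarsal torsion
    angles from cylinder fits, and storage-corrected muscle architecture
    (volume, length, anatomical cross-sectional area) with body-mass
    normalization. Includes generators for synthetic articulating joints and
    muscle fixtures with analytically known viability and moment arms, so
    every pipeline stage can be validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
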