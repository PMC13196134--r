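---
title: "Quantifying hallucal grasping biomechanics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hallucal grasping biomechanics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`halluxrom` quantifies how much a first digit (hallux) can move at its
tarso-metatarsal joint and how well-equipped its intrinsic musculature is to
drive that motion.  Four quantities carry the analysis:

1. the **osteological range of motion (ROM)** — the set of joint poses at
   which the two bone surfaces do not interpenetrate;
2. the **pose-space volume** of that set, measured as a 3D alpha shape in
   cosine-corrected Euler coordinates (cubed degrees);
3. **instantaneous muscle moment arms (IMMAs)** about the joint's center of
   rotation at every viable pose;
4. **muscle architecture** — storage-corrected volume, length and
   anatomical cross-sectional area (ACSA), normalized by body mass — plus
   **metatarsal torsion** about the bone's long axis.

Because the bone and muscle surface models such analyses are usually run on
are shared only on request, the package ships generators for synthetic
joints and muscles with analytically known answers.  All validation in the
test suite and the acceptance script runs against those closed forms; this
vignette records the model, its assumptions, and the design decisions that
were genuinely open.

## The joint model and pose grid

A joint is two watertight triangle meshes in a forward-kinematic chain:
the proximal bone (entocuneiform) is fixed; the distal bone (metatarsal I)
rotates about a center of rotation (COR) estimated by fitting a sphere to
the articular curvature.  A joint coordinate system (JCS) sits at the COR.
Its x axis is perpendicular to the proximal articular surface; the y and z
axes follow one of two clade conventions (`primate_marsupial` or
`rodent_scandentian`), which swap whether the medio-lateral or
dorso-ventral anatomical plane carries y.  In both conventions rotation
about z is flexion-extension (FE), about y abduction-adduction (ABAD), and
about x inversion-eversion (IE), with positive angles denoting flexion,
adduction and eversion.

Poses are intrinsic Tait-Bryan z-y-x rotations: `Rz(z) %*% Ry(y) %*% Rx(x)`.
The z rotation carries the y and x axes with it, the y rotation carries x.
The grid spans 270 degrees of FE and 180 degrees each of ABAD and IE at a
fixed 5-degree step — 55 x 37 x 37 = 75,295 candidate poses.  The ranges
are centered symmetrically on the reference pose.  Centering is a design
decision, not given: the reference pose must be viable and interior to the
grid, and symmetric centering is the only anchor-free choice.

The reference (0/0/0) pose aligns the distal bone's proximal articular
frame with the JCS axes and preserves the interarticular spacing defined by
a gap sphere placed between the surfaces.  The package realizes "preserving
the spacing" as a translation along the JCS x axis that puts the distal
frame origin at the gap sphere's distal pole (`center + radius * x`).  The
original interactive placement cannot be reproduced exactly; any rule that
is a pure x-translation and keeps the reference pose collision-free is
faithful, and this one is the simplest.  Model construction fails loudly if
the reference pose interpenetrates.

```{r}
library(halluxrom)
bs <- make_ball_and_socket(opening_half_angle_deg = 35)
grid <- generate_pose_grid()          # 75,295 poses
table <- sweep_poses(bs$model, grid)  # code 1 = viable
```

### Collision testing

A pose is viable iff the transformed distal mesh does not interpenetrate
the proximal mesh.  Interpenetration is decided by a separating-axis test
over candidate triangle pairs pruned with a bounding-volume hierarchy, plus
ray-parity containment for the no-surface-crossing case.  Surface contact
within 1e-9 mm counts as interpenetration: the 5-degree grid makes exact
touching a measure-zero event, and a conservative call errs toward fewer
viable poses.  The sweep exploits grid coherence by retesting the triangle
that collided at the previous pose first; this changes nothing about the
labels, only the runtime.

Translational degrees of freedom are deliberately absent: the rig rotates
about a fixed COR.  Joints with substantial translation (sliding facets)
are outside the model.

### Disarticulation and inclusion

Hyper-flexed "viable" poses whose articular surfaces no longer face each
other are, in the original workflow, removed after visual inspection.  The
package represents that step as explicit FE thresholds
(`filter_disarticulated(table, z_positive_max =, z_negative_min =)`):
thresholding is configuration, not vision, and keeps reruns deterministic.
Specimens with fewer than 4 viable poses are excluded
(`check_inclusion`) — four non-coplanar points are the minimum for a 3D
alpha shape.  The engineered `make_two_pose_fixture()` exercises exactly
this path.

## Cosine correction and alpha-shape volumetrics

The z-y-x Euler chart does not have a uniform volume element: its Haar
density is `cos(y) dz dy dx`, so raw pose clouds overweight poses at large
|ABAD|.  The package applies `zcc = z * cos(y)`, `ycc = y`, `xcc = x` — the
rescaling of the first-rotation coordinate by the cosine of the second that
locally equalizes the volume element.  The correction is undefined beyond
the gimbal singularity, so inputs require |y| <= 90 degrees.  Two package
tests pin this choice down independently: rotations sampled uniformly from
the rotation group become uniform in (zcc, ycc) after correction
(chi-square), and the alpha-shape volume of a corrected analytic pose box
matches the integral of cos(y) over the box to within discretization error
(0.1% at the 5-degree step).

Volumes come from 3D alpha shapes: the Delaunay tetrahedralization of the
corrected cloud filtered to tetrahedra with circumradius <= alpha (closed
inequality, matching the usual "alpha radius" semantics).  The working
alpha is a dataset-level floor of 50 degrees unless the cloud's *critical
alpha* — the smallest alpha whose complex is a single face-connected region
containing every point — exceeds it, in which case the critical value is
used (`select_alpha`).  The floor is configurable per specimen because the
"majority of critical values" it summarizes is a dataset property.

Numerical notes: regular grids are maximally cospherical, the worst case
for incremental Delaunay.  Inputs are deduplicated (corrected poses at
y = ±90 all collapse to zcc = 0) and jittered by a fixed, reproducible
1e-6-of-diameter perturbation before tetrahedralization; at alpha = 50 the
volume effect is far below every tolerance used.  Coplanar clouds of >= 4
points report volume 0 with a warning rather than erroring, mirroring the
exclusion workflow; fewer than 4 distinct points is an error.

## Moment arms

A muscle is the infinite straight line through an origin locator (fixed to
the proximal bone) and an insertion locator (carried by the distal bone
through each pose).  The IMMA at a pose is the perpendicular distance from
the COR to that line; the nearest point may fall outside the
origin-insertion segment, and does so routinely at extreme poses.  No
wrapping surfaces or via points are modeled.  Model-unit distances convert
to mm by the specimen/model ratio of a landmark distance (calcaneal
tuberosity to fifth metatarso-phalangeal joint), `imma_mm = a/b *
imma_model`, and are normalized by muscle length to a unitless index.
Muscles with several heads are one `muscle_path` per head.

The three `make_muscle_fixture` kinds give closed forms: a line through the
COR (IMMA identically zero), a perpendicular line at offset d (reference
IMMA exactly d), and a planar rotating insertion at radius r with origin at
distance D (IMMA `D r |sin z| / sqrt(D^2 + r^2 - 2 D r cos z)`, argmax at
`acos(r/D)`, essentially 90 degrees of flexion for D >> r).

## Torsion

Metatarsal torsion is the unsigned rotation, about the bone's long axis, of
the distal (head) articular frame relative to the proximal one, in
[0, 180) degrees — magnitudes only, as torsion is conventionally reported.
Frames sit at articular-patch area centroids and share an x axis along the
centroid-to-centroid direction; that shared-x construction is a proxy for
an interactive alignment step that has no published construction rule.  The
remaining axes come from axis-seeded least-squares cylinder fits to the
articular curvature, projected orthogonal to x; the clade conventions swap
which frame axis (y or z) tracks which cylinder.  A cylinder axis within 5
degrees of the long axis makes the projection degenerate and errors.  The
seed axis is a required argument precisely so the nonlinear fit — unlike
interactive placement — is deterministic.  Round-trip tests recover
constructed twists across 0-90 degrees within 2 degrees (typically < 0.4).

## Muscle architecture

Raw segmented volumes are corrected for storage shrinkage by multiplicative
factors: 1.64 (short-term ethanol), 2.49 (long-term ethanol), 1.32 (over a
month of formalin); factors compose multiplicatively and short/long ethanol
are mutually exclusive.  Lengths are endpoint distances (plus a middle
landmark for curved bellies, summing the two segments); multi-belly muscles
report the mean.  `ACSA = volume / length`.  Normalization assumes
isometry: volume by mass^1, length by mass^0.33, ACSA by mass^0.66 — the
exponents are used verbatim as 0.33 and 0.66, since reported relative
values are printed under exactly those exponents.  Whether to normalize is
gated per muscle and metric by a two-sided Pearson correlation against body
mass, applied to muscles present in more than two species; the significance
threshold, not stated in the source workflow, is set to p < 0.05 (the
conventional level) and is configurable.  Report tables round relative
values to 3 decimals, the precision at which such values are quoted (e.g. a
0.16 mm^2 ACSA at 196.8 g or 175.0 g body mass both print as 0.005
mm^2/g^0.66).

## What the synthetic data do and do not show

The generators emulate: controllable angular clearance (ball-and-socket
with a conical opening; analytic viability `swing <= opening -
asin(shaft_radius / rim_radius)`), anisotropic FE/ABAD clearance (elliptical
cone opening standing in for a saddle articulation), muscle lines with
closed-form moment arms, twisted metatarsals, and specimen metadata with
log-uniform masses on 6-300 g and the three storage categories.  The
"saddle" is deliberately an idealization: it reproduces the *property*
that distinguishes saddle joints — independent, unequal per-axis clearances
— not their congruent hyperbolic surfaces.

Passing tests on these fixtures therefore show that the pipeline's
geometry, measure correction, and bookkeeping are right; they do not show
that real bone surfaces are segmented, repaired or landmarked well, and
they cannot reproduce per-specimen numbers that depend on CT meshes
(alpha-shape volumes of real joints, specimen IMMA maps).  Default mesh
resolution is about 5,000 triangles per bone — enough that tessellation
error (well under half a degree on clearance boundaries) is invisible at
the 5-degree grid; production scan meshes are typically ~30,000.

Problem sizes used by the test suite and acceptance script: full 75,295-
pose sweeps for the oracle-agreement, exclusion and anisotropy checks
(3 opening angles x 5 tessellation seeds for the ROM oracle in the tests,
3 x 3 in the acceptance script), 1000 random configurations for the IMMA
oracle, and 6 twist angles x 20 seeds (tests) or x 5 (script) for torsion.

## Known limitations

* Rotation-only kinematics about a fixed COR; no translational DOF.
* Straight-line muscle paths; no wrapping, pennation or force estimation
  (ACSA, not PCSA).
* Disarticulation is threshold-based, not a geometric facing test.
* The cosine correction is undefined beyond |ABAD| = 90 degrees, which the
  180-degree ABAD grid touches exactly at its endpoints; corrected clouds
  deduplicate the collapsed poses.
* Alpha-shape volumes on jittered grids are reproducible but carry an
  O(1e-6) relative perturbation; do not compare volumes at tighter
  precision.
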