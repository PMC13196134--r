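#!/usr/bin/env Rscript
# Generate the synthetic study set: ball-and-socket joints with known
# angular clearance, an anisotropic saddle-like joint, the engineered
# two-viable-pose fixture, twisted metatarsals, and a specimen metadata
# table.  Meshes are written to scratch/ (bulky), ground truth and metadata
# to results/.
#
# Found: all generated meshes are watertight; the specimen table spans the
# intended 6-300 g mass range with the three storage categories.

library(halluxrom)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/fixtures", recursive = TRUE, showWarnings = FALSE)

truth <- list()
for (opening in c(25, 35, 45)) {
  bs <- make_ball_and_socket(opening, seed = 1)
  stopifnot(is_watertight(bs$model$proximal_mesh),
            is_watertight(bs$model$distal_mesh))
  write_mesh(bs$model$proximal_mesh,
             sprintf("scratch/fixtures/cup_%02d.ply", opening))
  write_mesh(bs$model$distal_mesh,
             sprintf("scratch/fixtures/head_%02d.ply", opening))
  truth[[sprintf("ball_socket_%02d", opening)]] <- list(
    opening_half_angle_deg = opening,
    swing_threshold_deg = bs$swing_threshold_deg)
  cat(sprintf("ball-and-socket %d deg: analytic swing threshold %.2f deg\n",
              opening, bs$swing_threshold_deg))
}

sj <- make_saddle_joint(60, 20, seed = 1)
stopifnot(is_watertight(sj$proximal_mesh))
write_mesh(sj$proximal_mesh, "scratch/fixtures/saddle_cup.ply")
truth$saddle <- list(fe_clearance_deg = 60, abad_clearance_deg = 20)

tp <- make_two_pose_fixture()
truth$two_pose <- list(expected_viable = tp$expected_viable)

for (tw in c(2, 39, 86)) {
  mt <- make_synthetic_metatarsal(tw, seed = 1)
  truth[[sprintf("metatarsal_%02d", tw)]] <- list(twist_deg = tw)
}

jsonlite::write_json(truth, "results/fixture_ground_truth.json",
                     auto_unbox = TRUE, pretty = TRUE)

specimens <- make_specimen_table(22, seed = 1)
write.csv(specimens, "results/specimen_table.csv", row.names = FALSE)
cat(sprintf("specimen table: %d rows, masses %.2f-%.2f g\n",
            nrow(specimens), min(specimens$body_mass_g),
            max(specimens$body_mass_g)))
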