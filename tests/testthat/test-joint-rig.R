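# Joint model construction, pose grids, pose kinematics and the viability
# sweep.

test_that("pose grid has the documented size, center and error behavior", {
  g <- generate_pose_grid()
  expect_equal(nrow(g), 55 * 37 * 37)   # (270/5+1) * (180/5+1)^2
  expect_true(any(g$z_deg == 0 & g$y_deg == 0 & g$x_deg == 0))
  expect_equal(range(g$z_deg), c(-135, 135))
  expect_equal(range(g$y_deg), c(-90, 90))
  g2 <- generate_pose_grid(180, 180, 180, 90)
  expect_equal(nrow(g2), 27)
  expect_error(generate_pose_grid(step = 7), "divisible")
})

test_that("reference construction honors frame alignment and the gap sphere", {
  bs <- make_ball_and_socket(40, seed = 2)
  ref <- bs$model$reference_transform
  # fixture is authored in world pose: reference must be the identity
  expect_equal(ref$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ref$translation, c(0, 0, 0), tolerance = 1e-12)

  # distal mesh authored offset along x: reference is the pure translation
  # bringing its proximal frame origin back to the gap-sphere pole
  m0 <- bs$model
  shifted <- triangle_mesh(sweep(m0$distal_mesh$vertices, 2, c(2, 0, 0), "+"),
                           m0$distal_mesh$faces)
  id <- identity_frame()
  model <- build_joint_model(m0$proximal_mesh, shifted,
                             cor_sphere = sphere(c(0, 0, 0), 10),
                             gap_sphere = m0$gap_sphere,
                             articular_surface_frame = id,
                             metatarsal_proximal_frame = identity_frame(c(2, 0, 0)),
                             convention = "primate_marsupial")
  expect_equal(model$reference_transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(model$reference_transform$translation, c(-2, 0, 0),
               tolerance = 1e-9)

  # an oversized head collides at reference and must refuse to build
  big <- triangle_mesh(m0$distal_mesh$vertices * 1.12, m0$distal_mesh$faces)
  expect_error(build_joint_model(m0$proximal_mesh, big,
                                 cor_sphere = sphere(c(0, 0, 0), 10),
                                 gap_sphere = m0$gap_sphere,
                                 articular_surface_frame = id,
                                 metatarsal_proximal_frame = id,
                                 convention = "primate_marsupial"),
               "reference pose")
})

test_that("pose_transform is the reference at 0/0/0 and an isometry about the COR", {
  set.seed(61)
  B <- random_rotation()
  cor <- c(2, -1, 3)
  ref <- rigid_transform(random_rotation(), c(0.3, -0.2, 0.5))
  model <- kinematic_model(cor = cor, jcs_basis = B, reference = ref)
  tf0 <- pose_transform(model, c(0, 0, 0))
  expect_equal(tf0$rotation, ref$rotation, tolerance = 1e-12)
  expect_equal(tf0$translation, ref$translation, tolerance = 1e-12)

  pts <- matrix(runif(30, -5, 5), ncol = 3)
  ref_pos <- transform_points(ref, pts)
  d_ref <- sqrt(rowSums(sweep(ref_pos, 2, cor)^2))
  for (i in 1:10) {
    pose <- runif(3, -120, 120)
    tfp <- pose_transform(model, pose)
    d <- sqrt(rowSums(sweep(transform_points(tfp, pts), 2, cor)^2))
    expect_equal(d, d_ref, tolerance = 1e-9)
  }
})

test_that("pose_transform rotates about world z when JCS is the world frame", {
  model <- kinematic_model()
  tf <- pose_transform(model, c(90, 0, 0))
  expect_equal(as.numeric(tf$rotation %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("classify_pose matches the analytic cone clearance on the fixture", {
  bs <- make_ball_and_socket(30, seed = 1)
  expect_equal(classify_pose(bs$model, c(0, 0, 0)), 1L)  # reference viable
  expect_equal(classify_pose(bs$model, c(10, 0, 0)), 1L)
  expect_equal(classify_pose(bs$model, c(50, 0, 0)), 0L)
})

test_that("sweep agrees with the analytic predicate on a coarse grid", {
  bs <- make_ball_and_socket(35, seed = 4)
  g <- generate_pose_grid(step = 15)
  tab <- sweep_poses(bs$model, g)
  pred <- bs$predicate(g$z_deg, g$y_deg, g$x_deg)
  expect_gte(mean((tab$code == 1L) == pred), 0.95)
  # symmetry of the viable set under z -> -z (axisymmetric fixture)
  key <- paste(tab$z_deg, tab$y_deg, tab$x_deg)
  mirrored <- paste(-tab$z_deg, tab$y_deg, tab$x_deg)
  expect_identical(tab$code, tab$code[match(key, mirrored)])
})

test_that("viability is invariant under a joint rigid transform of the model", {
  bs <- make_ball_and_socket(30, seed = 5, mesh_resolution = 1200)
  tf <- rigid_transform(quat_rot_zyx(20, 35, -50), c(5, -3, 2))
  m <- bs$model
  B2 <- tf$rotation %*% m$jcs$basis
  moved <- halluxrom:::.new_joint_model(
    proximal_mesh = transform_mesh(m$proximal_mesh, tf),
    distal_mesh = m$distal_mesh,
    cor = transform_points(tf, m$cor),
    jcs = frame(transform_points(tf, m$cor), B2[, 1], B2[, 2], B2[, 3]),
    gap_sphere = sphere(transform_points(tf, m$gap_sphere$center),
                        m$gap_sphere$radius),
    convention = m$convention,
    reference_transform = compose_transforms(tf, m$reference_transform))
  for (pose in list(c(0, 0, 0), c(15, 5, 30), c(30, -10, 0), c(60, 0, 0),
                    c(-25, 20, -45))) {
    expect_identical(classify_pose(moved, pose), classify_pose(m, pose))
  }
})

test_that("enlarging the opening never shrinks the viable set", {
  g <- generate_pose_grid(step = 15)
  narrow <- sweep_poses(make_ball_and_socket(25, seed = 6,
                                             mesh_resolution = 1200)$model, g)
  wide <- sweep_poses(make_ball_and_socket(45, seed = 6,
                                           mesh_resolution = 1200)$model, g)
  expect_true(all(wide$code >= narrow$code))
})

test_that("disarticulation thresholds recode only out-of-range viable poses", {
  tab <- structure(data.frame(z_deg = c(55, 65, -60, 0), y_deg = 0, x_deg = 0,
                              code = 1L, disarticulated = FALSE),
                   class = c("pose_viability", "data.frame"))
  out <- filter_disarticulated(tab, z_positive_max = 60)
  expect_equal(out$code, c(1L, 0L, 1L, 1L))
  expect_equal(out$disarticulated, c(FALSE, TRUE, FALSE, FALSE))
  out2 <- filter_disarticulated(out, z_negative_min = -55)
  expect_equal(out2$code, c(1L, 0L, 0L, 1L))
  out3 <- filter_disarticulated(tab)
  expect_identical(as.data.frame(out3), as.data.frame(tab))
})

test_that("inclusion rule excludes specimens below four viable poses", {
  two <- data.frame(z_deg = c(0, 5), y_deg = 0, x_deg = 0, code = 1L,
                    disarticulated = FALSE)
  expect_false(suppressMessages(check_inclusion(two)))
  none <- data.frame(z_deg = 0, y_deg = 0, x_deg = 0, code = 0L,
                     disarticulated = FALSE)
  expect_false(suppressMessages(check_inclusion(none)))
  four <- data.frame(z_deg = c(0, 5, 0, 0), y_deg = c(0, 0, 5, 0),
                     x_deg = c(0, 0, 0, 5), code = 1L, disarticulated = FALSE)
  inc <- check_inclusion(four)
  expect_true(inc)
  expect_equal(attr(inc, "n_viable"), 4L)
})
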