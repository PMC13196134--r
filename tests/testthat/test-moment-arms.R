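# Instantaneous muscle moment arms: per-pose values, unit conversion,
# normalization and the field over viable poses.

test_that("imma_at_pose reproduces simple closed-form configurations", {
  model <- kinematic_model()
  # line x = 10 in the z = 0 plane: distance from the origin COR is 10
  m <- muscle_path("m", origin_point = c(10, 0, 0),
                   insertion_point = c(10, 5, 0), muscle_length = 30)
  expect_equal(imma_at_pose(model, m, c(0, 0, 0)), 10)
  # line through the COR
  thru <- muscle_path("t", origin_point = c(-3, -3, -3),
                      insertion_point = c(3, 3, 3), muscle_length = 30)
  expect_equal(imma_at_pose(model, thru, c(0, 0, 0)), 0)
})

test_that("imma matches the cross-product closed form on random configurations", {
  set.seed(81)
  for (i in 1:200) {
    B <- random_rotation()
    cor <- runif(3, -5, 5)
    ref <- rigid_transform(random_rotation(), runif(3, -2, 2))
    model <- kinematic_model(cor = cor, jcs_basis = B, reference = ref)
    m <- muscle_path("m", origin_point = runif(3, -10, 10),
                     insertion_point = runif(3, -10, 10), muscle_length = 25)
    pose <- runif(3, -90, 90)
    got <- imma_at_pose(model, m, pose)
    # independent computation: rotation about the COR composed by hand
    Rw <- B %*% quat_rot_zyx(pose[1], pose[2], pose[3]) %*% t(B)
    ins <- as.numeric(Rw %*% (ref$rotation %*% m$insertion_point +
                                ref$translation - cor)) + cor
    u <- ins - m$origin_point
    w <- cor - m$origin_point
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    oracle <- sqrt(sum(cr^2)) / sqrt(sum(u^2))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("imma is invariant under a joint rigid transform of model and muscle", {
  set.seed(82)
  for (i in 1:20) {
    B <- random_rotation()
    cor <- runif(3, -5, 5)
    ref <- rigid_transform(random_rotation(), runif(3, -2, 2))
    model <- kinematic_model(cor = cor, jcs_basis = B, reference = ref)
    m <- muscle_path("m", runif(3, -10, 10), runif(3, -10, 10), 25)
    pose <- runif(3, -90, 90)
    tf <- random_rigid()
    B2 <- tf$rotation %*% B
    moved <- kinematic_model(cor = transform_points(tf, cor), jcs_basis = B2,
                             reference = compose_transforms(tf, ref))
    m2 <- muscle_path("m", transform_points(tf, m$origin_point),
                      m$insertion_point, 25)
    expect_equal(imma_at_pose(model, m, pose),
                 imma_at_pose(moved, m2, pose), tolerance = 1e-9)
  }
})

test_that("scaling and normalization are the stated arithmetic", {
  expect_equal(scale_imma(2, scale_factor(30, 15)), 4)
  expect_equal(scale_imma(1.7, scale_factor(12, 12)), 1.7)
  expect_error(scale_factor(30, 0), "positive")
  set.seed(83)
  for (i in 1:20) {
    v <- runif(1, 0, 10); a <- runif(1, 1, 50); b <- runif(1, 1, 50)
    expect_equal(scale_imma(v, scale_factor(a, b)), a / b * v)
  }
  expect_equal(normalize_imma(3, 30), 0.1)
  expect_equal(normalize_imma(0, 17), 0)
  expect_equal(normalize_imma(6, 60), normalize_imma(3, 30))
  expect_error(normalize_imma(3, 0), "positive")
})

test_that("imma_field reports per-pose records and the argmax pose", {
  model <- kinematic_model()
  sc <- scale_factor(20, 10)
  one <- data.frame(z_deg = 10, y_deg = 0, x_deg = 0, code = 1L,
                    disarticulated = FALSE)
  m <- muscle_path("m", c(10, 0, 0), c(10, 5, 0), 30)
  fld <- imma_field(model, m, one, sc)
  expect_equal(nrow(fld$records), 1)
  expect_equal(fld$argmax$z_deg, 10)
  expect_equal(fld$records$imma_mm, 2 * fld$records$imma_model)
  expect_equal(fld$records$imma_norm, fld$records$imma_mm / 30)

  # through-COR muscle: the whole field is exactly zero
  tab <- data.frame(z_deg = seq(-60, 60, 5), y_deg = 0, x_deg = 0,
                    code = 1L, disarticulated = FALSE)
  fx <- make_muscle_fixture(model, "through_cor")
  fld0 <- imma_field(model, fx$muscle, tab, sc)
  expect_true(all(fld0$records$imma_model == 0))

  # planar fixture: argmax within one grid step of the analytic optimum
  pc <- make_muscle_fixture(model, "planar_cosine", r = 5, D = 5000)
  tabz <- data.frame(z_deg = seq(-135, 135, 5), y_deg = 0, x_deg = 0,
                     code = 1L, disarticulated = FALSE)
  fldp <- imma_field(model, pc$muscle, tabz, sc)
  expect_lte(min(abs(abs(fldp$argmax$z_deg) - pc$z_star_deg)), 5)
  expect_true(all(is.finite(fldp$records$imma_norm)))
  expect_true(all(fldp$records$imma_norm >= 0))
  expect_error(imma_field(model, m, one[0, ], sc), "no viable poses")
})

test_that("perpendicular fixture gives its offset at the reference pose", {
  bs <- make_ball_and_socket(40, seed = 3, mesh_resolution = 1200)
  fx <- make_muscle_fixture(bs$model, "perpendicular_at_d", d = 7)
  expect_equal(imma_at_pose(bs$model, fx$muscle, c(0, 0, 0)), 7,
               tolerance = 1e-9)
})

test_that("imma is bounded by the insertion radius from the COR", {
  model <- kinematic_model()
  r <- 5
  pc <- make_muscle_fixture(model, "planar_cosine", r = r, D = 5000)
  for (z in seq(-135, 135, 15)) {
    expect_lte(imma_at_pose(model, pc$muscle, c(z, 0, 0)), r + 1e-9)
  }
})
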