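# Independent oracles and fixture helpers shared across the test files.
# Each oracle is implemented from first principles, independently of the
# package code paths it checks.

# --- quaternion composition oracle for intrinsic z-y-x rotations ---------

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_axis <- function(angle_deg, axis) {
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

quat_rot_zyx <- function(z_deg, y_deg, x_deg) {
  q <- quat_mul(quat_mul(quat_axis(z_deg, c(0, 0, 1)),
                         quat_axis(y_deg, c(0, 1, 0))),
                quat_axis(x_deg, c(1, 0, 0)))
  quat_to_matrix(q)
}

# --- separating-axis triangle-triangle oracle ----------------------------

sat_tri_tri <- function(t1, t2, tol = 1e-9) {
  e1 <- list(t1[2, ] - t1[1, ], t1[3, ] - t1[2, ], t1[1, ] - t1[3, ])
  e2 <- list(t2[2, ] - t2[1, ], t2[3, ] - t2[2, ], t2[1, ] - t2[3, ])
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(e1[[1]], e1[[2]])
  n2 <- cr(e2[[1]], e2[[2]])
  axes <- c(list(n1, n2),
            unlist(lapply(e1, function(a) lapply(e2, function(b) cr(a, b))),
                   recursive = FALSE),
            lapply(e1, function(a) cr(n1, a)),
            lapply(e2, function(b) cr(n2, b)))
  for (ax in axes) {
    nn <- sqrt(sum(ax^2))
    if (nn < 1e-12) next
    p1 <- t1 %*% ax
    p2 <- t2 %*% ax
    if (max(p1) < min(p2) - tol * nn || max(p2) < min(p1) - tol * nn) {
      return(FALSE)
    }
  }
  TRUE
}

# --- geometric fixture helpers -------------------------------------------

unit_cube_mesh <- function(center = c(0, 0, 0), side = 1) {
  m <- halluxrom:::.box_mesh(c(-side / 2, side / 2), c(-side / 2, side / 2),
                             c(-side / 2, side / 2))
  triangle_mesh(sweep(m$vertices, 2, center, "+"), m$faces)
}

random_rotation <- function() {
  q <- rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

random_rigid <- function(scale = 10) {
  rigid_transform(random_rotation(), runif(3, -scale, scale))
}

identity_frame <- function(origin = c(0, 0, 0)) {
  frame(origin, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# minimal joint model for kinematics-only tests: two tiny far-apart cubes
# so collisions never interfere, with configurable JCS and reference
kinematic_model <- function(cor = c(0, 0, 0), jcs_basis = diag(3),
                            reference = rigid_transform()) {
  jcs <- frame(cor, jcs_basis[, 1], jcs_basis[, 2], jcs_basis[, 3])
  halluxrom:::.new_joint_model(
    proximal_mesh = unit_cube_mesh(cor + c(500, 0, 0), 0.5),
    distal_mesh = unit_cube_mesh(c(-500, 0, 0), 0.5),
    cor = cor, jcs = jcs, gap_sphere = sphere(cor + c(1, 0, 0), 0.5),
    convention = "primate_marsupial", reference_transform = reference,
    check_reference = FALSE)
}

# analytic viability for the two-bone ball-and-socket fixture
swing_deg <- function(z_deg, y_deg) {
  acos(pmin(1, pmax(-1, cos(z_deg * pi / 180) * cos(y_deg * pi / 180)))) *
    180 / pi
}

# convex-hull volumes computed with an independent computational-geometry
# library (frozen): quasirandom cloud (i*sqrt(2) %% 1, i*sqrt(3) %% 1,
# i*sqrt(5) %% 1), i = 1..500, and the cosine-corrected 5-degree box grid
# z in [-60, 60], y in [-40, 40], x in [-30, 30]
HULL_VOL_QUASI_500 <- 0.9023677370583362
HULL_VOL_CC_BOX <- 530001.2415490922

quasirandom_cloud <- function(n = 500) {
  i <- seq_len(n)
  cbind((i * sqrt(2)) %% 1, (i * sqrt(3)) %% 1, (i * sqrt(5)) %% 1)
}

cc_box_grid <- function() {
  expand.grid(z_deg = seq(-60, 60, 5), y_deg = seq(-40, 40, 5),
              x_deg = seq(-30, 30, 5))
}
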