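# Synthetic joints, muscle fixtures, metatarsals and specimen metadata with
# analytically known ground truth.  These generators define the validation
# conditions for every pipeline stage: collision sweeps are checked against
# closed-form clearance predicates, moment arms against closed-form
# distances, torsion against constructed twists.
#
# All randomness is drawn from a local, seeded generator; the caller's RNG
# state is preserved and identical seeds regenerate fixtures bit-identically.

.with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

# ------------------------------------------------- mesh primitives -------

# closed axis-aligned box; faces oriented outward
.box_mesh <- function(xlim, ylim, zlim) {
  v <- as.matrix(expand.grid(x = xlim, y = ylim, z = zlim,
                             KEEP.OUT.ATTRS = FALSE))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = zlim[1]
    c(5, 6, 7), c(6, 8, 7),   # z = zlim[2]
    c(1, 2, 5), c(2, 6, 5),   # y = ylim[1]
    c(3, 7, 4), c(4, 7, 8),   # y = ylim[2]
    c(1, 5, 3), c(3, 5, 7),   # x = xlim[1]
    c(2, 4, 6), c(4, 8, 6)    # x = xlim[2]
  )
  triangle_mesh(v, f)
}

# closed prism over an annular sector in the x-y plane, extruded in z;
# radial faces lie exactly in the theta = th0 and theta = th1 planes
.sector_prism <- function(r0, r1, th0_deg, th1_deg, z0, z1, n = 24) {
  th <- seq(th0_deg, th1_deg, length.out = n + 1) * DEG
  inner <- cbind(r0 * cos(th), r0 * sin(th))
  outer <- cbind(r1 * cos(th), r1 * sin(th))
  ring <- rbind(inner, outer)   # 2*(n+1) points
  nv <- nrow(ring)
  v <- rbind(cbind(ring, z0), cbind(ring, z1))
  ii <- function(i) i            # inner index at level 0
  oi <- function(i) n + 1 + i    # outer index at level 0
  f <- list()
  for (i in 1:n) {
    a <- ii(i); b <- oi(i); c2 <- oi(i + 1); d <- ii(i + 1)
    # bottom cap (z = z0), facing -z
    f[[length(f) + 1]] <- rbind(c(a, c2, b), c(a, d, c2))
    # top cap (z = z1), facing +z
    f[[length(f) + 1]] <- rbind(c(a, b, c2) + nv, c(a, c2, d) + nv)
    # inner wall
    f[[length(f) + 1]] <- rbind(c(a, a + nv, d), c(d, a + nv, d + nv))
    # outer wall
    f[[length(f) + 1]] <- rbind(c(b, c2, b + nv), c(c2, c2 + nv, b + nv))
  }
  # radial end walls at th0 (i = 1 edge) and th1 (i = n+1 edge)
  a <- ii(1); b <- oi(1)
  f[[length(f) + 1]] <- rbind(c(a, b, a + nv), c(b, b + nv, a + nv))
  a <- ii(n + 1); b <- oi(n + 1)
  f[[length(f) + 1]] <- rbind(c(a, a + nv, b), c(b, a + nv, b + nv))
  triangle_mesh(v, do.call(rbind, f))
}

# direction on the unit sphere; theta = polar angle from +x, phi = azimuth
# in the (y, z) plane measured from +y
.sph_dir <- function(theta, phi) {
  cbind(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
}

# Closed cup shell: the solid between radii R_in and R_in + thickness over
# polar angles theta >= theta_rim(phi), with a rim annulus closing the
# opening.  theta_rim_fn takes azimuth (radians) and returns the rim polar
# angle (radians).
.cup_mesh <- function(theta_rim_fn, R_in, thickness, nphi = 48, ntheta = 16,
                      phase = 0) {
  R_out <- R_in + thickness
  phi <- phase + 2 * pi * (0:(nphi - 1)) / nphi
  th_rim <- vapply(phi, theta_rim_fn, numeric(1))
  # rows of the lateral grids: fraction 0 (rim) .. 1 (pole, excluded)
  fr <- (0:(ntheta - 1)) / ntheta
  vs <- list(); idx_in <- matrix(0L, ntheta, nphi); idx_out <- idx_in
  cnt <- 0L
  for (i in 1:ntheta) {
    th <- th_rim + (pi - th_rim) * fr[i]
    d <- .sph_dir(th, phi)
    vs[[length(vs) + 1]] <- R_in * d
    idx_in[i, ] <- cnt + 1:nphi; cnt <- cnt + nphi
  }
  for (i in 1:ntheta) {
    th <- th_rim + (pi - th_rim) * fr[i]
    d <- .sph_dir(th, phi)
    vs[[length(vs) + 1]] <- R_out * d
    idx_out[i, ] <- cnt + 1:nphi; cnt <- cnt + nphi
  }
  pole_in <- cnt + 1L; pole_out <- cnt + 2L
  v <- rbind(do.call(rbind, vs), c(-R_in, 0, 0), c(-R_out, 0, 0))
  jn <- function(j) if (j == nphi) 1L else j + 1L
  f <- vector("list", 0)
  for (i in 1:(ntheta - 1)) {
    for (j in 1:nphi) {
      j2 <- jn(j)
      a <- idx_in[i, j]; b <- idx_in[i + 1, j]
      c2 <- idx_in[i + 1, j2]; d <- idx_in[i, j2]
      f[[length(f) + 1]] <- rbind(c(a, b, c2), c(a, c2, d))
      a <- idx_out[i, j]; b <- idx_out[i + 1, j]
      c2 <- idx_out[i + 1, j2]; d <- idx_out[i, j2]
      f[[length(f) + 1]] <- rbind(c(a, c2, b), c(a, d, c2))
    }
  }
  for (j in 1:nphi) {
    j2 <- jn(j)
    f[[length(f) + 1]] <- rbind(
      c(idx_in[ntheta, j], pole_in, idx_in[ntheta, j2]),
      c(idx_out[ntheta, j], idx_out[ntheta, j2], pole_out),
      # rim annulus between inner and outer rim rings
      c(idx_in[1, j], idx_in[1, j2], idx_out[1, j]),
      c(idx_in[1, j2], idx_out[1, j2], idx_out[1, j]))
  }
  triangle_mesh(v, do.call(rbind, f))
}

# Closed head-plus-shaft: sphere of radius rh centered at the origin with
# the polar cap around +x removed at angle beta = asin(s/rh), continued by a
# cylindrical shaft of radius s along +x to x = L, with a flat end cap.
.head_shaft_mesh <- function(rh, s, L, nphi = 48, ntheta = 12, nshaft = 6,
                             phase = 0) {
  stopifnot(s < rh, L > rh)
  beta <- asin(s / rh)
  phi <- phase + 2 * pi * (0:(nphi - 1)) / nphi
  fr <- (0:(ntheta - 1)) / ntheta
  vs <- list(); cnt <- 0L
  idx_sph <- matrix(0L, ntheta, nphi)
  for (i in 1:ntheta) {
    th <- beta + (pi - beta) * fr[i]
    vs[[length(vs) + 1]] <- rh * .sph_dir(th, phi)
    idx_sph[i, ] <- cnt + 1:nphi; cnt <- cnt + nphi
  }
  x0 <- rh * cos(beta)
  xs <- seq(x0, L, length.out = nshaft + 1)[-1]
  idx_shaft <- matrix(0L, nshaft, nphi)
  for (i in 1:nshaft) {
    vs[[length(vs) + 1]] <- cbind(xs[i], s * cos(phi), s * sin(phi))
    idx_shaft[i, ] <- cnt + 1:nphi; cnt <- cnt + nphi
  }
  pole <- cnt + 1L; cap_center <- cnt + 2L
  v <- rbind(do.call(rbind, vs), c(-rh, 0, 0), c(L, 0, 0))
  jn <- function(j) if (j == nphi) 1L else j + 1L
  band <- function(top, bot) {
    out <- vector("list", nphi)
    for (j in 1:nphi) {
      j2 <- jn(j)
      out[[j]] <- rbind(c(top[j], bot[j], bot[j2]), c(top[j], bot[j2], top[j2]))
    }
    do.call(rbind, out)
  }
  f <- list()
  for (i in 1:(ntheta - 1)) f[[length(f) + 1]] <- band(idx_sph[i, ], idx_sph[i + 1, ])
  # sphere pole fan
  for (j in 1:nphi) {
    f[[length(f) + 1]] <- rbind(c(idx_sph[ntheta, j], pole, idx_sph[ntheta, jn(j)]))
  }
  # shaft bands: sphere rim ring (row 1) up to the far ring
  f[[length(f) + 1]] <- band(idx_shaft[1, ], idx_sph[1, ])
  if (nshaft > 1) {
    for (i in 1:(nshaft - 1)) {
      f[[length(f) + 1]] <- band(idx_shaft[i + 1, ], idx_shaft[i, ])
    }
  }
  # end cap fan
  for (j in 1:nphi) {
    f[[length(f) + 1]] <- rbind(c(idx_shaft[nshaft, j], idx_shaft[nshaft, jn(j)],
                                  cap_center))
  }
  triangle_mesh(v, do.call(rbind, f))
}

# open spherical-cap patch around `axis` with the given half-angle
.spherical_cap_mesh <- function(radius, center, axis, half_angle, nphi = 32,
                                nrings = 8) {
  axis <- .unit3(axis)
  h <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- .unit3(.cross3(axis, h)); e2 <- .cross3(axis, e1)
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  vs <- list(center + radius * axis)
  idx <- matrix(0L, nrings, nphi); cnt <- 1L
  for (i in 1:nrings) {
    th <- half_angle * i / nrings
    ring <- t(sapply(phi, function(p) {
      center + radius * (cos(th) * axis + sin(th) * (cos(p) * e1 + sin(p) * e2))
    }))
    vs[[length(vs) + 1]] <- ring
    idx[i, ] <- cnt + 1:nphi; cnt <- cnt + nphi
  }
  v <- do.call(rbind, vs)
  jn <- function(j) if (j == nphi) 1L else j + 1L
  f <- list()
  for (j in 1:nphi) f[[length(f) + 1]] <- rbind(c(1L, idx[1, j], idx[1, jn(j)]))
  for (i in 1:(nrings - 1)) {
    for (j in 1:nphi) {
      j2 <- jn(j)
      f[[length(f) + 1]] <- rbind(c(idx[i, j], idx[i + 1, j], idx[i + 1, j2]),
                                  c(idx[i, j], idx[i + 1, j2], idx[i, j2]))
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

# merge meshes (possibly multiple closed components) into one triangle_mesh
.merge_meshes <- function(...) {
  ms <- list(...)
  offs <- 0L; vs <- list(); fs <- list()
  for (m in ms) {
    vs[[length(vs) + 1]] <- m$vertices
    fs[[length(fs) + 1]] <- m$faces + offs
    offs <- offs + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

# azimuthal resolution from a triangle-count target: the cup uses about
# 4 * nphi * ntheta triangles with ntheta = nphi / 3
.nphi_from_resolution <- function(mesh_resolution) {
  max(24L, min(160L, as.integer(round(sqrt(0.75 * mesh_resolution)))))
}

# ------------------------------------------------- joint generators ------

#' Synthetic ball-and-socket joint with analytic viability
#'
#' Proximal bone: hemispherical cup (inner radius `head_radius`) with a
#' conical opening of the given half-angle around the JCS x axis.  Distal
#' bone: sphere of radius `head_radius - gap` continued by a cylindrical
#' shaft of radius `shaft_radius` exiting through the opening along x at the
#' reference pose.  A pose is analytically viable iff the shaft swing angle
#' from the opening axis satisfies
#' `swing <= opening_half_angle - asin(shaft_radius / head_radius)`; the
#' swing of pose (z, y, x) is `acos(cos z cos y)` (IE spins the shaft about
#' its own axis and never limits motion here).
#'
#' @param opening_half_angle_deg cone opening half-angle, degrees (5-80).
#' @param head_radius cup inner radius, mm.
#' @param gap radial articular clearance, mm (> 0).
#' @param shaft_radius shaft radius, mm (< head_radius).
#' @param shaft_length shaft length from the head center, mm; must clear the
#'   cup wall.
#' @param mesh_resolution target triangle count per bone.
#' @param seed tessellation seed (azimuthal phase); geometry is unchanged.
#' @param cup_thickness cup wall thickness, mm.
#' @return List: `model` (a `joint_model`), `predicate` (vectorized
#'   `function(z_deg, y_deg, x_deg)` returning analytic viability),
#'   `swing_threshold_deg`.
#' @export
make_ball_and_socket <- function(opening_half_angle_deg, head_radius = 10,
                                 gap = 0.5, shaft_radius = 1.2,
                                 shaft_length = 18, mesh_resolution = 5000,
                                 seed = 1, cup_thickness = 2) {
  stopifnot(opening_half_angle_deg >= 5, opening_half_angle_deg <= 80,
            gap > 0, shaft_radius < head_radius,
            shaft_length > head_radius + cup_thickness)
  margin <- asin(shaft_radius / head_radius) / DEG
  if (opening_half_angle_deg <= margin) {
    stop("opening too narrow for the shaft: reference pose would collide")
  }
  nphi <- .nphi_from_resolution(mesh_resolution)
  phase <- .with_local_seed(seed, stats::runif(1, 0, 2 * pi / nphi))
  alpha <- opening_half_angle_deg * DEG
  cup <- .cup_mesh(function(phi) alpha, head_radius, cup_thickness,
                   nphi = nphi, ntheta = max(8L, nphi %/% 3), phase = phase)
  head <- .head_shaft_mesh(head_radius - gap, shaft_radius, shaft_length,
                           nphi = nphi, ntheta = max(8L, nphi %/% 4),
                           phase = phase)
  id <- frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  model <- build_joint_model(
    proximal_mesh = cup, distal_mesh = head,
    cor_sphere = sphere(c(0, 0, 0), head_radius),
    gap_sphere = sphere(c(-gap, 0, 0), gap),
    articular_surface_frame = id, metatarsal_proximal_frame = id,
    convention = "primate_marsupial")
  threshold <- opening_half_angle_deg - margin
  predicate <- function(z_deg, y_deg, x_deg) {
    swing <- acos(pmin(1, pmax(-1, cos(z_deg * DEG) * cos(y_deg * DEG)))) / DEG
    swing <= threshold
  }
  list(model = model, predicate = predicate, swing_threshold_deg = threshold)
}

#' Synthetic anisotropic ("saddle-like") joint
#'
#' A ball head in a socket whose opening is an elliptical cone: the angular
#' clearance is `fe_clearance_deg` for pure flexion-extension (rotation
#' about z, which swings the shaft in the x-y plane) and
#' `abad_clearance_deg` for pure abduction-adduction (rotation about y),
#' interpolating elliptically in between.  This reproduces the anisotropy of
#' saddle-shaped joints, where FE is typically less restricted than ABAD,
#' with a construction whose per-axis clearances are controlled
#' independently and monotonically.
#'
#' @param fe_clearance_deg,abad_clearance_deg angular clearances (degrees)
#'   for FE and ABAD.
#' @param congruence_depth cup shell thickness, mm.
#' @inheritParams make_ball_and_socket
#' @return A `joint_model`.
#' @export
make_saddle_joint <- function(fe_clearance_deg, abad_clearance_deg,
                              congruence_depth = 2, head_radius = 10,
                              gap = 0.5, shaft_radius = 1.2,
                              shaft_length = 18, mesh_resolution = 5000,
                              seed = 1) {
  stopifnot(fe_clearance_deg > 0, abad_clearance_deg > 0,
            fe_clearance_deg < 85, abad_clearance_deg < 85)
  margin <- asin(shaft_radius / head_radius) / DEG
  if (min(fe_clearance_deg, abad_clearance_deg) <= margin) {
    stop("clearance too small for the shaft: reference pose would collide")
  }
  nphi <- .nphi_from_resolution(mesh_resolution)
  phase <- .with_local_seed(seed, stats::runif(1, 0, 2 * pi / nphi))
  tf <- tan(fe_clearance_deg * DEG)
  ta <- tan(abad_clearance_deg * DEG)
  rim <- function(phi) {
    atan(1 / sqrt((cos(phi) / tf)^2 + (sin(phi) / ta)^2))
  }
  cup <- .cup_mesh(rim, head_radius, congruence_depth, nphi = nphi,
                   ntheta = max(8L, nphi %/% 3), phase = phase)
  head <- .head_shaft_mesh(head_radius - gap, shaft_radius, shaft_length,
                           nphi = nphi, ntheta = max(8L, nphi %/% 4),
                           phase = phase)
  id <- frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  build_joint_model(
    proximal_mesh = cup, distal_mesh = head,
    cor_sphere = sphere(c(0, 0, 0), head_radius),
    gap_sphere = sphere(c(-gap, 0, 0), gap),
    articular_surface_frame = id, metatarsal_proximal_frame = id,
    convention = "primate_marsupial")
}

#' Engineered fixture with exactly two viable poses
#'
#' A thin blade articulating in a slotted socket: parallel slabs stop any
#' inversion-eversion or abduction-adduction, and radial stop walls confine
#' flexion-extension so that exactly the poses (0, 0, 0) and (5, 0, 0) of
#' the default 5-degree grid are collision-free.  Used to exercise the
#' minimum-viable-pose exclusion rule.
#'
#' @return List: `model` (a `joint_model`) and `expected_viable` (2).
#' @export
make_two_pose_fixture <- function() {
  blade <- .box_mesh(c(0.5, 10), c(-1, 1), c(-0.15, 0.15))
  prox <- .merge_meshes(
    .box_mesh(c(-12, 12), c(-12, 12), c(0.2, 3)),      # upper slab
    .box_mesh(c(-12, 12), c(-12, 12), c(-3, -0.2)),    # lower slab
    .sector_prism(8, 12, 12.5, 180, -0.18, 0.18, n = 48),   # flexion stop
    .sector_prism(8, 12, -180, -7.5, -0.18, 0.18, n = 48)   # extension stop
  )
  id <- frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  model <- .new_joint_model(
    proximal_mesh = prox, distal_mesh = blade, cor = c(0, 0, 0), jcs = id,
    gap_sphere = sphere(c(-0.25, 0, 0), 0.25),
    convention = "primate_marsupial",
    reference_transform = rigid_transform())
  list(model = model, expected_viable = 2L)
}

# ------------------------------------------------ muscle fixtures --------

#' Synthetic muscle fixtures with analytic moment arms
#'
#' Builds a [muscle_path] for a given joint model whose IMMA has a closed
#' form:
#' * `through_cor`: the line of action passes through the COR at every pose;
#'   IMMA is identically 0.
#' * `perpendicular_at_d`: at the reference pose the line runs parallel to
#'   the JCS z axis at offset `d` along y; the reference IMMA is exactly
#'   `d`.
#' * `planar_cosine`: insertion at radius `r` from the COR in the FE (z
#'   rotation) plane, origin far along +x at distance `D`; for pose
#'   (z, 0, 0) the IMMA is `D*r*|sin z| / sqrt(D^2 + r^2 - 2*D*r*cos z)`,
#'   maximized at `z* = acos(r/D)` (close to 90 degrees for `D >> r`).
#'
#' @param model a `joint_model`.
#' @param kind `"through_cor"`, `"perpendicular_at_d"` or `"planar_cosine"`.
#' @param d offset (model units) for `perpendicular_at_d`.
#' @param r insertion radius for `planar_cosine`.
#' @param D origin distance for `planar_cosine`.
#' @param muscle_length length used for normalization, mm.
#' @return List: `muscle` (a [muscle_path]), `analytic` (function of
#'   `(z_deg, y_deg, x_deg)` returning the exact IMMA in model units, or
#'   `NA` where no closed form is provided), and for `planar_cosine`
#'   `z_star_deg` (the analytic argmax).
#' @export
make_muscle_fixture <- function(model, kind = c("through_cor",
                                                "perpendicular_at_d",
                                                "planar_cosine"),
                                d = 7, r = 5, D = 5000, muscle_length = 30) {
  kind <- match.arg(kind)
  B <- model$jcs$basis
  cor <- model$cor
  inv_ref <- invert_transform(model$reference_transform)
  loc <- function(world) transform_points(inv_ref, world)
  if (kind == "through_cor") {
    muscle <- muscle_path("through_cor",
                          origin_point = cor + as.numeric(B %*% c(-20, 3, 1)),
                          insertion_point = loc(cor),
                          muscle_length = muscle_length)
    analytic <- function(z_deg, y_deg, x_deg) 0 * z_deg
    return(list(muscle = muscle, analytic = analytic))
  }
  if (kind == "perpendicular_at_d") {
    muscle <- muscle_path("perpendicular_at_d",
                          origin_point = cor + as.numeric(B %*% c(0, d, -10)),
                          insertion_point = loc(cor + as.numeric(B %*% c(0, d, 10))),
                          muscle_length = muscle_length)
    analytic <- function(z_deg, y_deg, x_deg) {
      ifelse(z_deg == 0 & y_deg == 0 & x_deg == 0, d, NA_real_)
    }
    return(list(muscle = muscle, analytic = analytic, d = d))
  }
  muscle <- muscle_path("planar_cosine",
                        origin_point = cor + as.numeric(B %*% c(D, 0, 0)),
                        insertion_point = loc(cor + as.numeric(B %*% c(r, 0, 0))),
                        muscle_length = muscle_length)
  analytic <- function(z_deg, y_deg, x_deg) {
    ifelse(y_deg == 0 & x_deg == 0,
           D * r * abs(sin(z_deg * DEG)) /
             sqrt(D^2 + r^2 - 2 * D * r * cos(z_deg * DEG)),
           NA_real_)
  }
  list(muscle = muscle, analytic = analytic,
       z_star_deg = acos(r / D) / DEG, r = r, D = D)
}

# ------------------------------------------- torsion fixture -------------

#' Synthetic metatarsal for torsion recovery
#'
#' A straight bone of the given length along x whose distal (head) cylinder
#' axis is twisted by `twist_deg` about the long axis relative to the
#' proximal cylinder axis.  Articular patches are spherical caps centered
#' on the long axis; cylinder surfaces are sampled with Gaussian noise for
#' the fits.
#'
#' @param twist_deg ground-truth torsion angle, degrees in \[0, 180).
#' @param seed RNG seed for the surface sampling noise.
#' @param bone_length length between patch apices, mm.
#' @param head_radius,prox_radius cylinder radii, mm.
#' @param noise_sd Gaussian noise on the sampled cylinder points, mm.
#' @param n_points sample size per cylinder.
#' @param convention clade convention for the frame assignment.
#' @return List with `proximal_patch`, `distal_patch` ([articular_patch]),
#'   `head_points`, `proximal_points` (noisy surface samples),
#'   `head_axis_init`, `proximal_axis_init` (perturbed seed axes),
#'   `twist_deg`, `convention`.
#' @export
make_synthetic_metatarsal <- function(twist_deg, seed = 1, bone_length = 20,
                                      head_radius = 1.5, prox_radius = 1.8,
                                      noise_sd = 0.01, n_points = 200,
                                      convention = "primate_marsupial") {
  .check_convention(convention)
  stopifnot(twist_deg >= 0, twist_deg < 180)
  L <- bone_length
  rc <- 3
  prox_patch <- articular_patch(.spherical_cap_mesh(
    rc, center = c(rc, 0, 0), axis = c(-1, 0, 0), half_angle = 40 * DEG))
  dist_patch <- articular_patch(.spherical_cap_mesh(
    rc, center = c(L - rc, 0, 0), axis = c(1, 0, 0), half_angle = 40 * DEG))
  tw <- twist_deg * DEG
  # head cylinder axis: y rotated by the twist about the long (x) axis for
  # the primate/marsupial convention (distal y tracks the head cylinder),
  # z rotated for the rodent/scandentian convention (distal z tracks it)
  base_axis <- if (convention == "primate_marsupial") c(0, 1, 0) else c(0, 0, 1)
  head_axis <- c(0,
                 cos(tw) * base_axis[2] - sin(tw) * base_axis[3],
                 sin(tw) * base_axis[2] + cos(tw) * base_axis[3])
  prox_axis <- if (convention == "primate_marsupial") c(0, 0, 1) else c(0, 1, 0)
  sample_cyl <- function(axis_point, axis_dir, radius) {
    axis_dir <- .unit3(axis_dir)
    h <- if (abs(axis_dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- .unit3(.cross3(axis_dir, h)); e2 <- .cross3(axis_dir, e1)
    t <- stats::runif(n_points, -1, 1)
    ang <- stats::runif(n_points, 0, 140 * DEG)
    pts <- t(vapply(seq_len(n_points), function(i) {
      axis_point + t[i] * axis_dir +
        radius * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
    }, numeric(3)))
    pts + matrix(stats::rnorm(3 * n_points, 0, noise_sd), ncol = 3)
  }
  .with_local_seed(seed, {
    head_points <- sample_cyl(c(L, 0, 0), head_axis, head_radius)
    prox_points <- sample_cyl(c(0, 0, 0), prox_axis, prox_radius)
    head_init <- .unit3(head_axis + stats::rnorm(3, 0, 0.05))
    prox_init <- .unit3(prox_axis + stats::rnorm(3, 0, 0.05))
    list(proximal_patch = prox_patch, distal_patch = dist_patch,
         head_points = head_points, proximal_points = prox_points,
         head_axis_init = head_init, proximal_axis_init = prox_init,
         twist_deg = twist_deg, convention = convention)
  })
}

# ------------------------------------------- specimen metadata -----------

#' Synthetic specimen metadata table
#'
#' Emulates a small-mammal comparative sample: body masses drawn log-uniform
#' on \[6, 300\] g (the span of the study animals), preservation states in
#' the three storage categories (fresh-frozen, short-term ethanol, long-term
#' ethanol, short-term ethanol plus formalin), and clade tags carrying the
#' joint-axis convention.  Deterministic per seed.
#'
#' @param n_specimens number of specimens (>= 1).
#' @param seed RNG seed.
#' @return Data frame with columns `specimen`, `species`, `clade`,
#'   `convention`, `body_mass_g`, `ethanol_short`, `ethanol_long`,
#'   `formalin_month`.
#' @export
make_specimen_table <- function(n_specimens, seed = 1) {
  if (n_specimens < 1) stop("n_specimens must be >= 1")
  clades <- c(strepsirrhine = "primate_marsupial",
              platyrrhine = "primate_marsupial",
              scandentian = "rodent_scandentian",
              rodent = "rodent_scandentian",
              marsupial = "primate_marsupial")
  .with_local_seed(seed, {
    clade <- sample(names(clades), n_specimens, replace = TRUE)
    mass <- round(exp(stats::runif(n_specimens, log(6), log(300))), 2)
    pres <- sample(c("none", "ethanol_short", "ethanol_long",
                     "ethanol_short_formalin"), n_specimens, replace = TRUE,
                   prob = c(0.6, 0.15, 0.15, 0.1))
    data.frame(
      specimen = sprintf("SYN_%03d", seq_len(n_specimens)),
      species = sprintf("Synthetica %s", clade),
      clade = clade,
      convention = unname(clades[clade]),
      body_mass_g = mass,
      ethanol_short = pres %in% c("ethanol_short", "ethanol_short_formalin"),
      ethanol_long = pres == "ethanol_long",
      formalin_month = pres == "ethanol_short_formalin")
  })
}
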