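# Forward-kinematic joint model, pose grid generation, and the
# collision-based viability sweep.
#
# Pose convention: z = flexion-extension (FE), y = abduction-adduction
# (ABAD), x = inversion-eversion (IE); positive z/y/x = flexion, adduction,
# eversion.  Rotations are intrinsic z-y-x about the center of rotation
# (COR), expressed in the joint coordinate system (JCS) axes.

.CONVENTIONS <- c("primate_marsupial", "rodent_scandentian")

.check_convention <- function(convention) {
  if (!is.character(convention) || length(convention) != 1 ||
      !(convention %in% .CONVENTIONS)) {
    stop("convention must be one of: ", paste(.CONVENTIONS, collapse = ", "))
  }
  convention
}

#' Build a forward-kinematic joint model
#'
#' Assembles the proximal (fixed) and distal (mobile) bone meshes, the
#' center of rotation, and the joint coordinate system into the object all
#' range-of-motion and moment-arm operations act on.  The JCS sits at the
#' center of the COR sphere with axes taken from `articular_surface_frame`
#' (x perpendicular to the articular surface, y/z per the clade convention).
#'
#' The reference (0/0/0) pose is constructed by rotating the distal mesh so
#' the axes of its proximal coordinate frame coincide with the JCS axes, then
#' translating along the JCS x axis so the distal frame origin sits at the
#' distal pole of the interarticular gap sphere
#' (`gap_sphere$center + gap_sphere$radius * x`), preserving the spacing the
#' gap sphere defines.  Construction fails if the reference pose
#' interpenetrates: every usable joint model has a viable reference pose.
#'
#' @param proximal_mesh watertight [triangle_mesh] of the fixed bone
#'   (entocuneiform side).
#' @param distal_mesh watertight [triangle_mesh] of the mobile bone
#'   (metatarsal), in its own local coordinates.
#' @param cor_sphere [sphere] fitted to the articular curvature; its center
#'   is the COR.
#' @param gap_sphere [sphere] defining the interarticular spacing.
#' @param articular_surface_frame [frame] giving the JCS axes.
#' @param metatarsal_proximal_frame [frame] attached to the distal bone's
#'   proximal articular surface, in distal-mesh local coordinates.
#' @param convention `"primate_marsupial"` or `"rodent_scandentian"`.
#' @return Object of class `joint_model`.
#' @export
build_joint_model <- function(proximal_mesh, distal_mesh, cor_sphere,
                              gap_sphere, articular_surface_frame,
                              metatarsal_proximal_frame, convention) {
  stopifnot(inherits(proximal_mesh, "triangle_mesh"),
            inherits(distal_mesh, "triangle_mesh"),
            inherits(cor_sphere, "sphere"), inherits(gap_sphere, "sphere"),
            inherits(articular_surface_frame, "frame"),
            inherits(metatarsal_proximal_frame, "frame"))
  .check_convention(convention)
  cor <- cor_sphere$center
  jcs <- frame(cor, articular_surface_frame$basis[, 1],
               articular_surface_frame$basis[, 2],
               articular_surface_frame$basis[, 3])
  # rotation aligning the metatarsal frame axes onto the JCS axes
  R <- jcs$basis %*% t(metatarsal_proximal_frame$basis)
  target <- gap_sphere$center + gap_sphere$radius * jcs$basis[, 1]
  tr <- target - as.numeric(R %*% metatarsal_proximal_frame$origin)
  reference <- rigid_transform(R, tr)
  model <- structure(list(proximal_mesh = proximal_mesh,
                          distal_mesh = distal_mesh,
                          cor = cor, jcs = jcs, gap_sphere = gap_sphere,
                          convention = convention,
                          reference_transform = reference),
                     class = "joint_model")
  if (meshes_interpenetrate(proximal_mesh,
                            transform_mesh(distal_mesh, reference))) {
    stop("reference pose interpenetrates; all reference poses must be viable")
  }
  model
}

# internal constructor for synthetic fixtures that are authored directly in
# world coordinates (reference transform supplied, viability still enforced)
.new_joint_model <- function(proximal_mesh, distal_mesh, cor, jcs, gap_sphere,
                             convention, reference_transform,
                             check_reference = TRUE) {
  model <- structure(list(proximal_mesh = proximal_mesh,
                          distal_mesh = distal_mesh,
                          cor = as.numeric(cor), jcs = jcs,
                          gap_sphere = gap_sphere, convention = convention,
                          reference_transform = reference_transform),
                     class = "joint_model")
  if (check_reference &&
      meshes_interpenetrate(proximal_mesh,
                            transform_mesh(distal_mesh, reference_transform))) {
    stop("reference pose interpenetrates; all reference poses must be viable")
  }
  model
}

#' @export
print.joint_model <- function(x, ...) {
  cat("joint_model (", x$convention, ")\n", sep = "")
  cat("  proximal:", nrow(x$proximal_mesh$faces), "faces; distal:",
      nrow(x$distal_mesh$faces), "faces\n")
  cat("  COR: (", paste(signif(x$cor, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Generate the pose grid
#'
#' Regular grid of z-y-x (FE/ABAD/IE) rotations centered symmetrically on
#' the reference pose, endpoints inclusive.  Defaults follow the study
#' conditions: 270 degrees of FE and 180 degrees of ABAD and IE at a fixed
#' 5-degree step, i.e. 55 x 37 x 37 = 75,295 candidate poses.
#'
#' @param fe_range,abad_range,ie_range total range (degrees) for z, y, x.
#' @param step grid step in degrees; each range must be divisible by it.
#' @return Data frame of class `pose_grid` with columns `z_deg`, `y_deg`,
#'   `x_deg`; x varies fastest, then y, then z.
#' @export
generate_pose_grid <- function(fe_range = 270, abad_range = 180,
                               ie_range = 180, step = 5) {
  stopifnot(step > 0)
  for (r in c(fe_range, abad_range, ie_range)) {
    if (abs(r / step - round(r / step)) > 1e-9) {
      stop("ranges must be divisible by the step size")
    }
  }
  z <- seq(-fe_range / 2, fe_range / 2, by = step)
  y <- seq(-abad_range / 2, abad_range / 2, by = step)
  x <- seq(-ie_range / 2, ie_range / 2, by = step)
  g <- expand.grid(x_deg = x, y_deg = y, z_deg = z,
                   KEEP.OUT.ATTRS = FALSE)[, c("z_deg", "y_deg", "x_deg")]
  rownames(g) <- NULL
  structure(g, step = step,
            ranges = c(fe = fe_range, abad = abad_range, ie = ie_range),
            class = c("pose_grid", "data.frame"))
}

# world rotation matrices (n x 9, row-major) for pose angles about the COR
# expressed in JCS axes: Rw = B Rzyx B'
.pose_world_rotations <- function(model, z, y, x) {
  cz <- cos(z * DEG); sz <- sin(z * DEG)
  cy <- cos(y * DEG); sy <- sin(y * DEG)
  cx <- cos(x * DEG); sx <- sin(x * DEG)
  n <- length(z)
  Rl <- list(
    cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
    sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
    -sy,     cy * sx,                cy * cx
  )
  B <- model$jcs$basis
  out <- matrix(0, n, 9)
  for (i in 1:3) for (l in 1:3) {
    acc <- numeric(n)
    for (j in 1:3) for (k in 1:3) {
      acc <- acc + B[i, j] * Rl[[(j - 1) * 3 + k]] * B[l, k]
    }
    out[, (i - 1) * 3 + l] <- acc
  }
  out
}

#' Rigid transform realizing a pose
#'
#' Pure rotation about the COR (in JCS axes) composed after the reference
#' transform; maps distal-mesh local coordinates to world coordinates at the
#' given pose.  `pose = c(0, 0, 0)` returns the reference transform itself.
#'
#' @param model a `joint_model`.
#' @param pose numeric `c(z_deg, y_deg, x_deg)`.
#' @return A [rigid_transform].
#' @export
pose_transform <- function(model, pose) {
  stopifnot(inherits(model, "joint_model"), length(pose) == 3)
  B <- model$jcs$basis
  Rw <- B %*% .rot_zyx(pose[1], pose[2], pose[3]) %*% t(B)
  ref <- model$reference_transform
  rigid_transform(
    rotation = Rw %*% ref$rotation,
    translation = as.numeric(Rw %*% (ref$translation - model$cor)) + model$cor
  )
}

#' Classify a single pose as viable or non-viable
#'
#' @param model a `joint_model`.
#' @param pose numeric `c(z_deg, y_deg, x_deg)`.
#' @return 1 if the bones do not interpenetrate at the pose, else 0.
#' @export
classify_pose <- function(model, pose) {
  tf <- pose_transform(model, pose)
  hit <- meshes_interpenetrate(model$proximal_mesh,
                               transform_mesh(model$distal_mesh, tf))
  if (hit) 0L else 1L
}

#' Sweep a pose grid for collision viability
#'
#' Tests every grid pose for bone-bone interpenetration and codes it 1
#' (viable, no intersection) or 0 (non-viable).  The distal mesh is rotated
#' about the COR per pose; the proximal mesh is held fixed.
#'
#' @param model a `joint_model`.
#' @param grid a [generate_pose_grid()] result (or any data frame with
#'   `z_deg`, `y_deg`, `x_deg`).
#' @param verbose log progress every 10,000 poses.
#' @return Data frame of class `pose_viability` with columns `z_deg`,
#'   `y_deg`, `x_deg`, `code`, `disarticulated` (all FALSE here), one row
#'   per grid pose in grid order.
#' @export
sweep_poses <- function(model, grid, verbose = FALSE) {
  stopifnot(inherits(model, "joint_model"))
  rot <- .pose_world_rotations(model, grid$z_deg, grid$y_deg, grid$x_deg)
  ref <- model$reference_transform
  code <- cpp_sweep_collide(model$proximal_mesh$vertices,
                            model$proximal_mesh$faces,
                            model$distal_mesh$vertices,
                            model$distal_mesh$faces,
                            rot, model$cor, ref$rotation, ref$translation,
                            verbose)
  out <- data.frame(z_deg = grid$z_deg, y_deg = grid$y_deg,
                    x_deg = grid$x_deg, code = as.integer(code),
                    disarticulated = FALSE)
  if (verbose) {
    message(sprintf("sweep: %d / %d poses viable", sum(out$code == 1L),
                    nrow(out)))
  }
  structure(out, class = c("pose_viability", "data.frame"))
}

#' Flag disarticulated poses beyond FE thresholds
#'
#' Viable poses with z beyond the given flexion/extension thresholds are
#' flagged `disarticulated` and recoded 0, mirroring the visual-inspection
#' step in which hyper-flexed poses whose articular surfaces no longer face
#' each other are removed.
#'
#' @param table a `pose_viability` table.
#' @param z_positive_max flag viable poses with `z_deg` above this value
#'   (degrees), or `NULL` for no positive threshold.
#' @param z_negative_min flag viable poses with `z_deg` below this value,
#'   or `NULL`.
#' @return The table with updated `code` and `disarticulated` columns.
#' @export
filter_disarticulated <- function(table, z_positive_max = NULL,
                                  z_negative_min = NULL) {
  stopifnot(is.data.frame(table))
  flag <- rep(FALSE, nrow(table))
  if (!is.null(z_positive_max)) flag <- flag | table$z_deg > z_positive_max
  if (!is.null(z_negative_min)) flag <- flag | table$z_deg < z_negative_min
  flag <- flag & table$code == 1L
  table$disarticulated <- table$disarticulated | flag
  table$code[flag] <- 0L
  table
}

#' Inclusion check for pose-space analysis
#'
#' A specimen is excluded when it has fewer viable (non-disarticulated)
#' poses than `min_viable`; four non-coplanar points are the minimum for a
#' 3D alpha shape.
#'
#' @param table a `pose_viability` table.
#' @param min_viable minimum viable pose count (default 4).
#' @return Logical: include the specimen?  The viable count is attached as
#'   attribute `n_viable`.
#' @export
check_inclusion <- function(table, min_viable = 4) {
  n <- sum(table$code == 1L & !table$disarticulated)
  ok <- n >= min_viable
  if (!ok) {
    message(sprintf(
      "excluded from pose-space analysis: %d viable pose(s) < %d", n,
      min_viable))
  }
  structure(ok, n_viable = n)
}

#' Extract viable poses from a viability table
#' @param table a `pose_viability` table.
#' @return Data frame of the viable, non-disarticulated poses.
#' @export
viable_poses <- function(table) {
  table[table$code == 1L & !table$disarticulated,
        c("z_deg", "y_deg", "x_deg"), drop = FALSE]
}
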