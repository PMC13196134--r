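# Instantaneous muscle moment arms (IMMAs) about the COR.
#
# A muscle is modelled as the infinite straight line of action through its
# origin (fixed in the proximal frame) and insertion (carried by the distal
# bone).  The IMMA at a pose is the perpendicular distance from the COR to
# that line; the nearest point may fall outside the origin-insertion
# segment.  Model-unit values are converted to mm with a specimen/model
# landmark ratio and normalized by muscle length for comparison.

#' Muscle path (straight line of action)
#'
#' @param name muscle name.
#' @param origin_point length-3 origin locator, fixed in world (proximal)
#'   coordinates.
#' @param insertion_point length-3 insertion locator in distal-mesh local
#'   coordinates; it is carried through each pose by [pose_transform()].
#' @param muscle_length muscle length in mm (> 0), used for normalization.
#' @return Object of class `muscle_path`.
#' @export
muscle_path <- function(name, origin_point, insertion_point, muscle_length) {
  stopifnot(length(origin_point) == 3, length(insertion_point) == 3,
            muscle_length > 0)
  structure(list(name = name, origin_point = as.numeric(origin_point),
                 insertion_point = as.numeric(insertion_point),
                 muscle_length = muscle_length),
            class = "muscle_path")
}

#' Model-to-specimen scale factor
#'
#' Ratio of the distance between the calcaneal tuberosity and the fifth
#' metatarso-phalangeal joint measured on the specimen (`a_mm`) and on the
#' model (`b_model`): IMMA (mm) = a/b * IMMA (model units).
#'
#' @param a_mm landmark distance on the specimen, mm (> 0).
#' @param b_model same landmark distance in model units (> 0).
#' @export
scale_factor <- function(a_mm, b_model) {
  if (!(a_mm > 0)) stop("a_mm must be positive")
  if (!(b_model > 0)) stop("b_model must be positive")
  structure(list(a_mm = a_mm, b_model = b_model), class = "scale_factor")
}

#' IMMA at a single pose (model units)
#'
#' @param model a `joint_model`.
#' @param muscle a [muscle_path].
#' @param pose numeric `c(z_deg, y_deg, x_deg)`; should be a viable pose.
#' @return Perpendicular distance from the COR to the muscle's line of
#'   action, in model units.
#' @export
imma_at_pose <- function(model, muscle, pose) {
  tf <- pose_transform(model, pose)
  ins <- transform_points(tf, muscle$insertion_point)
  if (sqrt(sum((ins - muscle$origin_point)^2)) < 1e-12) {
    stop("origin and insertion coincide at this pose")
  }
  point_line_distance(model$cor, muscle$origin_point, ins)$distance
}

#' Convert IMMA from model units to mm
#'
#' @param imma_model_units IMMA in model units.
#' @param scale a [scale_factor].
#' @export
scale_imma <- function(imma_model_units, scale) {
  stopifnot(inherits(scale, "scale_factor"))
  (scale$a_mm / scale$b_model) * imma_model_units
}

#' Normalize IMMA by muscle length
#'
#' @param imma_mm IMMA in mm.
#' @param muscle_length muscle length in mm (> 0).
#' @return Unitless normalized IMMA.
#' @export
normalize_imma <- function(imma_mm, muscle_length) {
  if (!all(muscle_length > 0)) stop("muscle length must be positive")
  imma_mm / muscle_length
}

#' IMMA field over the viable poses
#'
#' Computes the moment arm of one muscle at every viable, non-disarticulated
#' pose of a viability table, converts to mm and normalizes by muscle
#' length, and reports the pose(s) attaining the maximum normalized IMMA
#' (ties all reported).
#'
#' @param model a `joint_model`.
#' @param muscle a [muscle_path].
#' @param table a `pose_viability` table with at least one viable pose.
#' @param scale a [scale_factor].
#' @param corrected_cloud optional [cosine_correct()] result for the same
#'   table; its coordinates are joined onto the records.
#' @return List with `records` (one row per viable pose: pose angles,
#'   corrected coordinates if supplied, `imma_model`, `imma_mm`,
#'   `imma_norm`) and `argmax` (rows attaining the maximum `imma_norm`).
#' @export
imma_field <- function(model, muscle, table, scale, corrected_cloud = NULL) {
  vp <- viable_poses(table)
  if (nrow(vp) == 0) stop("no viable poses in table")
  rot <- .pose_world_rotations(model, vp$z_deg, vp$y_deg, vp$x_deg)
  ref <- model$reference_transform
  p_ref <- as.numeric(ref$rotation %*% muscle$insertion_point +
                        ref$translation) - model$cor
  # insertion world position per pose: cor + Rw %*% p_ref
  ins <- cbind(rot[, 1] * p_ref[1] + rot[, 2] * p_ref[2] + rot[, 3] * p_ref[3],
               rot[, 4] * p_ref[1] + rot[, 5] * p_ref[2] + rot[, 6] * p_ref[3],
               rot[, 7] * p_ref[1] + rot[, 8] * p_ref[2] + rot[, 9] * p_ref[3])
  ins <- sweep(ins, 2, model$cor, "+")
  a <- muscle$origin_point
  u <- sweep(ins, 2, a)          # line directions
  w <- model$cor - a
  un2 <- rowSums(u^2)
  if (any(un2 < 1e-24)) stop("origin and insertion coincide at a pose")
  tpar <- (u[, 1] * w[1] + u[, 2] * w[2] + u[, 3] * w[3]) / un2
  nearest <- sweep(u * tpar, 2, a, "+")
  d_model <- sqrt((nearest[, 1] - model$cor[1])^2 +
                  (nearest[, 2] - model$cor[2])^2 +
                  (nearest[, 3] - model$cor[3])^2)
  d_mm <- scale_imma(d_model, scale)
  d_norm <- normalize_imma(d_mm, muscle$muscle_length)
  rec <- data.frame(z_deg = vp$z_deg, y_deg = vp$y_deg, x_deg = vp$x_deg)
  if (!is.null(corrected_cloud)) {
    stopifnot(nrow(corrected_cloud) == nrow(rec))
    rec$zcc <- corrected_cloud$zcc
    rec$ycc <- corrected_cloud$ycc
    rec$xcc <- corrected_cloud$xcc
  }
  rec$imma_model <- d_model
  rec$imma_mm <- d_mm
  rec$imma_norm <- d_norm
  mx <- max(d_norm)
  list(records = rec,
       argmax = rec[d_norm >= mx - 1e-12, , drop = FALSE],
       max_imma_norm = mx, muscle = muscle$name)
}
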