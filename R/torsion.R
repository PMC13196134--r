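# Metatarsal torsion: the rotation (angle alpha) of the bone's distal
# (head) articular frame about the long axis relative to its proximal
# articular frame.  Frames are anchored at articular-patch centroids with a
# shared x axis along the long (centroid-to-centroid) axis; the remaining
# axes come from cylinder fits to the articular curvature, assigned per
# clade convention.

#' Articular surface patch
#'
#' @param mesh a [triangle_mesh].
#' @param face_indices indices of the faces forming the patch (>= 1).
#' @return Object of class `articular_patch` with area-weighted `centroid`
#'   (mm) and `area` (mm^2).
#' @export
articular_patch <- function(mesh, face_indices = seq_len(nrow(mesh$faces))) {
  face_indices <- as.integer(face_indices)
  if (length(face_indices) == 0) stop("empty face subset")
  stopifnot(all(face_indices >= 1), all(face_indices <= nrow(mesh$faces)))
  f <- mesh$faces[face_indices, , drop = FALSE]
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  total <- sum(areas)
  if (total <= 0) stop("patch has zero area")
  centroid <- colSums(((v1 + v2 + v3) / 3) * areas) / total
  structure(list(mesh = mesh, face_indices = face_indices,
                 centroid = as.numeric(centroid), area = total,
                 face_areas = areas),
            class = "articular_patch")
}

#' Area of an articular patch (mm^2)
#' @param patch an [articular_patch].
#' @export
patch_area <- function(patch) {
  stopifnot(inherits(patch, "articular_patch"))
  patch$area
}

#' Build proximal and distal epiphysis frames for torsion measurement
#'
#' Frame origins sit at the patch centroids; both frames share an x axis
#' along the bone's long axis (proximal-to-distal centroid direction).  The
#' remaining axes are set from the cylinder fits per clade convention and
#' completed right-handed after projecting the cylinder axes orthogonal to
#' x:
#' * `rodent_scandentian`: distal z parallel to the head cylinder axis,
#'   proximal y parallel to the proximal cylinder axis;
#' * `primate_marsupial`: distal y parallel to the head cylinder axis,
#'   proximal z parallel to the proximal cylinder axis.
#'
#' @param proximal_patch,distal_patch [articular_patch] objects.
#' @param head_cylinder,proximal_cylinder [cylinder] fits to the distal
#'   (head) and proximal articular curvature.
#' @param convention `"primate_marsupial"` or `"rodent_scandentian"`.
#' @return List with `proximal_frame` and `distal_frame` ([frame]s).
#' @export
build_epiphysis_frames <- function(proximal_patch, distal_patch,
                                   head_cylinder, proximal_cylinder,
                                   convention) {
  .check_convention(convention)
  stopifnot(inherits(head_cylinder, "cylinder"),
            inherits(proximal_cylinder, "cylinder"))
  cp <- proximal_patch$centroid
  cd <- distal_patch$centroid
  xhat <- .unit3(cd - cp)
  project <- function(axis) {
    axis <- .unit3(axis)
    ang <- acos(min(1, abs(sum(axis * xhat))))
    if (ang < 5 * DEG) {
      stop("cylinder axis within 5 degrees of the long axis: projection degenerate")
    }
    .unit3(axis - sum(axis * xhat) * xhat)
  }
  if (convention == "rodent_scandentian") {
    zd <- project(head_cylinder$axis_direction)
    distal <- frame(cd, xhat, .cross3(zd, xhat), zd)
    yp <- project(proximal_cylinder$axis_direction)
    proximal <- frame(cp, xhat, yp, .cross3(xhat, yp))
  } else {
    yd <- project(head_cylinder$axis_direction)
    distal <- frame(cd, xhat, yd, .cross3(xhat, yd))
    zp <- project(proximal_cylinder$axis_direction)
    proximal <- frame(cp, xhat, .cross3(zp, xhat), zp)
  }
  list(proximal_frame = proximal, distal_frame = distal)
}

#' Torsion angle between two frames sharing an x axis
#'
#' The unsigned rotation about the common x axis carrying the proximal
#' (y, z) axes onto the distal ones, in \[0, 180\] degrees; magnitudes only,
#' as torsion is conventionally reported.
#'
#' @param proximal_frame,distal_frame [frame]s whose x axes are parallel
#'   within `tol` radians.
#' @param tol tolerance on the x-axis alignment (radians).
#' @return Torsion angle alpha in degrees.
#' @export
torsion_angle <- function(proximal_frame, distal_frame, tol = 1e-6) {
  xp <- proximal_frame$basis[, 1]
  xd <- distal_frame$basis[, 1]
  if (acos(min(1, sum(xp * xd))) > tol) {
    stop("frames do not share a common x direction")
  }
  yp <- proximal_frame$basis[, 2]
  zp <- proximal_frame$basis[, 3]
  yd <- distal_frame$basis[, 2]
  a <- atan2(sum(xp * .cross3(yp, yd)), sum(yp * yd)) / DEG
  abs(a)
}
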