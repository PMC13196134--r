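# Cosine correction of Euler pose space, 3D alpha shapes, volumes in cubed
# degrees, and per-axis excursion summaries.
#
# The z-y-x Euler chart carries the volume element cos(y) dz dy dx, so raw
# pose clouds over-represent large |y|.  The correction zcc = z*cos(y),
# ycc = y, xcc = x rescales the first-rotation coordinate by the cosine of
# the second-rotation angle, locally equalizing the volume element; alpha
# shapes of corrected clouds are then comparable across joints.

#' Cosine-correct a pose cloud
#'
#' @param poses data frame with `z_deg`, `y_deg`, `x_deg` (degrees), or a
#'   `pose_viability` table, from which the viable, non-disarticulated poses
#'   are taken.  Angles must lie in (-180, 180\] with |y| <= 90 (beyond the
#'   gimbal singularity the correction is undefined).
#' @return Data frame of class `corrected_pose_cloud` with columns `zcc`,
#'   `ycc`, `xcc` (degrees).
#' @export
cosine_correct <- function(poses) {
  if (!is.null(poses$code)) poses <- viable_poses(poses)
  stopifnot(all(c("z_deg", "y_deg", "x_deg") %in% names(poses)))
  if (any(abs(poses$y_deg) > 90)) {
    stop("cosine correction undefined for |y| > 90 degrees")
  }
  if (any(poses$z_deg <= -180 | poses$z_deg > 180 |
          poses$x_deg <= -180 | poses$x_deg > 180)) {
    stop("pose angles must lie in (-180, 180]")
  }
  out <- data.frame(zcc = poses$z_deg * cos(poses$y_deg * DEG),
                    ycc = poses$y_deg, xcc = poses$x_deg)
  structure(out, class = c("corrected_pose_cloud", "data.frame"))
}

# Deduplicate, validate and symbolically jitter a point cloud for Delaunay
# tetrahedralization.  Regular grids are massively cospherical; a fixed,
# reproducible jitter of ~1e-6 of the cloud diameter breaks the ties without
# materially changing volumes or circumradii.  The caller's RNG state is
# left untouched.
.prep_points <- function(points, require_rank3 = TRUE) {
  P <- as.matrix(points[, 1:3])
  storage.mode(P) <- "double"
  if (any(!is.finite(P))) stop("degenerate input: non-finite coordinates")
  P <- P[!duplicated(round(P, 9)), , drop = FALSE]
  if (nrow(P) < 4) stop("degenerate input: fewer than 4 distinct points")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  diam <- 2 * sv[1] / sqrt(nrow(P)) + 1
  rank3 <- sv[3] > 1e-9 * max(sv[1], 1)
  if (require_rank3 && !rank3) {
    stop("degenerate input: points are coplanar (not affinely independent in 3D)")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(20260926L)
  J <- matrix(stats::rnorm(length(P), 0, 1e-6 * diam), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  list(points = P, jittered = P + J, rank3 = rank3)
}

#' Delaunay tetrahedralization of a 3D point cloud
#'
#' @param points n x 3 matrix or data frame (n >= 4, affinely independent).
#' @return List with `tets` (m x 4, 1-based indices into the deduplicated
#'   points), `circumradius`, `volume` per tetrahedron and `points` (the
#'   deduplicated input).
#' @export
delaunay_tetrahedra <- function(points) {
  pr <- .prep_points(points)
  d <- cpp_delaunay3(pr$jittered)
  d$points <- pr$points
  d
}

#' Critical alpha radius of a point cloud
#'
#' The smallest alpha for which the alpha complex is a single face-connected
#' region containing every input point, found by bisection over the sorted
#' tetrahedron circumradii.
#'
#' @param points n x 3 matrix or data frame, n >= 4, affinely independent.
#' @return Critical alpha (degrees, for pose clouds).
#' @export
critical_alpha <- function(points) {
  d <- delaunay_tetrahedra(points)
  ca <- cpp_critical_alpha(d$tets, d$circumradius, nrow(d$points))
  if (is.na(ca)) stop("no alpha yields a connected complex covering all points")
  ca
}

#' Select the alpha radius with a dataset floor
#'
#' The working alpha is the floor (default 50 degrees, the dataset-level
#' choice) unless the cloud's critical alpha exceeds it, in which case the
#' critical value is used instead.
#'
#' @param points n x 3 matrix or data frame.
#' @param floor minimum alpha radius (degrees).
#' @return Selected alpha, with the critical value attached as attribute
#'   `critical_alpha`.
#' @export
select_alpha <- function(points, floor = 50) {
  ca <- critical_alpha(points)
  structure(max(floor, ca), critical_alpha = ca)
}

#' 3D alpha shape of a point cloud
#'
#' Delaunay tetrahedralization filtered to tetrahedra with circumradius
#' <= `alpha_radius` (closed inequality); the shape's volume is the sum of
#' retained tetrahedron volumes.  For `alpha_radius` at or above the largest
#' circumradius the alpha shape is the convex hull.
#'
#' Coplanar clouds of 4+ points report volume 0 with a warning (flat pose
#' sets occur in excluded specimens); fewer than 4 distinct points is an
#' error.
#'
#' @param points n x 3 matrix or data frame (degrees for pose clouds).
#' @param alpha_radius positive alpha radius (degrees).
#' @return Object of class `alpha_shape_result`: `alpha_radius`, `volume`
#'   (cubed degrees), `simplices` (m x 4 indices), `n_points`.
#' @export
alpha_shape <- function(points, alpha_radius) {
  stopifnot(is.numeric(alpha_radius), alpha_radius > 0)
  pr <- .prep_points(points, require_rank3 = FALSE)
  if (!pr$rank3) {
    warning("coplanar point cloud: alpha shape volume is 0")
    return(structure(list(alpha_radius = alpha_radius,
                          critical_alpha = NA_real_, volume = 0,
                          simplices = matrix(integer(0), 0, 4),
                          n_points = nrow(pr$points)),
                     class = "alpha_shape_result"))
  }
  d <- cpp_delaunay3(pr$jittered)
  keep <- d$circumradius <= alpha_radius
  structure(list(alpha_radius = alpha_radius,
                 critical_alpha = attr(alpha_radius, "critical_alpha") %||%
                   NA_real_,
                 volume = sum(d$volume[keep]),
                 simplices = d$tets[keep, , drop = FALSE],
                 n_points = nrow(pr$points)),
            class = "alpha_shape_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alpha_shape_result <- function(x, ...) {
  cat(sprintf("alpha shape: alpha = %.4g, volume = %.6g deg^3, %d tetrahedra over %d points\n",
              x$alpha_radius, x$volume, nrow(x$simplices), x$n_points))
  if (!is.na(x$critical_alpha)) {
    cat(sprintf("  critical alpha = %.4g\n", x$critical_alpha))
  }
  invisible(x)
}

#' Per-axis excursion summary of a corrected pose cloud
#'
#' @param points data frame or matrix of cosine-corrected poses
#'   (`zcc`, `ycc`, `xcc`).
#' @return Data frame with `axis`, `min`, `max` (degrees) for cc-FE,
#'   cc-ABAD, cc-IE.
#' @export
excursion_summary <- function(points) {
  P <- as.matrix(points[, 1:3])
  if (nrow(P) < 1) stop("empty pose cloud")
  data.frame(axis = c("cc_fe", "cc_abad", "cc_ie"),
             min = apply(P, 2, min), max = apply(P, 2, max),
             row.names = NULL)
}

#' Full pose-space summary of a viability table
#'
#' Convenience wrapper: cosine-correct the viable poses, select the alpha
#' radius against the floor, build the alpha shape, and summarise
#' excursions.
#'
#' @param table a `pose_viability` table with at least 4 viable poses.
#' @param alpha_floor dataset-level alpha floor (degrees).
#' @return List: `cloud`, `alpha_radius`, `critical_alpha`,
#'   `volume_deg3`, `excursions`, `shape`.
#' @export
pose_space_summary <- function(table, alpha_floor = 50) {
  cloud <- cosine_correct(table)
  alpha <- select_alpha(cloud, floor = alpha_floor)
  shape <- alpha_shape(cloud, alpha)
  shape$critical_alpha <- attr(alpha, "critical_alpha")
  list(cloud = cloud, alpha_radius = as.numeric(alpha),
       critical_alpha = attr(alpha, "critical_alpha"),
       volume_deg3 = shape$volume,
       excursions = excursion_summary(cloud), shape = shape)
}
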