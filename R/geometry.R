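# Rotation algebra, primitive fitting, distances and mesh predicates.
# Units: lengths in mm (or grid degrees when used in pose space),
# angles in degrees at the interface, radians internally.

DEG <- pi / 180

.norm3 <- function(v) sqrt(sum(v^2))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix, orthonormal with determinant +1
#'   (checked to 1e-9).
#' @param translation length-3 numeric translation vector.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Intrinsic z-y-x (Tait-Bryan) rotation
#'
#' Composes Rz(z) %*% Ry(y) %*% Rx(x): an intrinsic rotation about z first,
#' which carries the y and x axes with it, then about the new y, then about
#' the newest x.  This is the convention in which the first rotation (z,
#' flexion-extension) re-orients the axes of the remaining two.
#'
#' @param z_deg,y_deg,x_deg rotation angles in degrees.
#' @return A [rigid_transform] with zero translation.
#' @export
rotation_zyx <- function(z_deg, y_deg, x_deg) {
  stopifnot(is.finite(z_deg), is.finite(y_deg), is.finite(x_deg))
  rigid_transform(rotation = .rot_zyx(z_deg, y_deg, x_deg))
}

# bare 3x3 matrix fast path
.rot_zyx <- function(z_deg, y_deg, x_deg) {
  cz <- cos(z_deg * DEG); sz <- sin(z_deg * DEG)
  cy <- cos(y_deg * DEG); sy <- sin(y_deg * DEG)
  cx <- cos(x_deg * DEG); sx <- sin(x_deg * DEG)
  matrix(c(
    cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
    sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
    -sy,     cy * sx,                cy * cx
  ), nrow = 3, byrow = TRUE)
}

#' Extract z-y-x Tait-Bryan angles from a rotation matrix
#'
#' Inverse of [rotation_zyx()]; `y` is returned in \[-90, 90\] degrees.
#'
#' @param rotation 3x3 rotation matrix or a [rigid_transform].
#' @return Named numeric vector `c(z_deg, y_deg, x_deg)`.
#' @export
euler_zyx <- function(rotation) {
  if (inherits(rotation, "rigid_transform")) rotation <- rotation$rotation
  sy <- -rotation[3, 1]
  sy <- min(1, max(-1, sy))
  y <- asin(sy)
  if (abs(abs(sy) - 1) < 1e-12) {
    # gimbal lock: put the whole in-plane rotation on z
    z <- atan2(-rotation[1, 2], rotation[2, 2])
    x <- 0
  } else {
    z <- atan2(rotation[2, 1], rotation[1, 1])
    x <- atan2(rotation[3, 2], rotation[3, 3])
  }
  c(z_deg = z / DEG, y_deg = y / DEG, x_deg = x / DEG)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform].
#' @param points numeric vector of length 3 or an n x 3 matrix.
#' @return Transformed points in the same shape as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) {
    as.numeric(transform$rotation %*% points + transform$translation)
  } else {
    sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
  }
}

#' Compose two rigid transforms
#'
#' `compose_transforms(f, g)` returns the transform applying `g` first and
#' then `f`.
#'
#' @param f,g [rigid_transform] objects.
#' @export
compose_transforms <- function(f, g) {
  rigid_transform(rotation = f$rotation %*% g$rotation,
                  translation = as.numeric(f$rotation %*% g$translation +
                                             f$translation))
}

#' Invert a rigid transform
#' @param transform a [rigid_transform].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(rotation = Rt,
                  translation = as.numeric(-Rt %*% transform$translation))
}

#' Orthonormal right-handed coordinate frame
#'
#' @param origin length-3 origin (mm).
#' @param axis_x,axis_y,axis_z unit axis vectors; must be mutually orthogonal
#'   within 1e-9 and right-handed (x cross y = z within 1e-9).
#' @return Object of class `frame` with a `basis` matrix whose columns are
#'   the axes.
#' @export
frame <- function(origin, axis_x, axis_y, axis_z) {
  B <- cbind(.unit3(axis_x), .unit3(axis_y), .unit3(axis_z))
  if (max(abs(crossprod(B) - diag(3))) > 1e-9) {
    stop("frame axes must be mutually orthogonal unit vectors")
  }
  if (max(abs(.cross3(B[, 1], B[, 2]) - B[, 3])) > 1e-9) {
    stop("frame must be right-handed (x cross y = z)")
  }
  structure(list(origin = as.numeric(origin), basis = B), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("frame at (", paste(signif(x$origin, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Sphere object
#' @param center length-3 center (mm).
#' @param radius positive radius (mm).
#' @param rms root-mean-square fit residual, if fitted.
#' @export
sphere <- function(center, radius, rms = NA_real_) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = radius, rms = rms),
            class = "sphere")
}

#' Cylinder object
#' @param axis_point point on the cylinder axis (mm).
#' @param axis_direction unit direction of the axis.
#' @param radius positive radius (mm).
#' @param rms root-mean-square radial residual, if fitted.
#' @export
cylinder <- function(axis_point, axis_direction, radius, rms = NA_real_) {
  stopifnot(length(axis_point) == 3, radius > 0)
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = .unit3(axis_direction),
                 radius = radius, rms = rms),
            class = "cylinder")
}

#' Algebraic least-squares sphere fit
#'
#' Solves the linear system |p|^2 = 2 c.p + (r^2 - |c|^2) in the
#' least-squares sense; exact on noiseless samples of a sphere.
#'
#' @param points n x 3 matrix, n >= 4, not all coplanar.
#' @return A [sphere] with the RMS of the radial residuals.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4) stop("ill-conditioned sphere fit: points are coplanar or degenerate")
  # guard against numerically near-coplanar input that qr still ranks full
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop("ill-conditioned sphere fit: points are coplanar or degenerate")
  }
  sol <- qr.coef(qrA, b)
  center <- sol[1:3]
  radius2 <- sol[4] + sum(center^2)
  if (radius2 <= 0) stop("ill-conditioned sphere fit: non-positive radius")
  r <- sqrt(radius2)
  res <- sqrt(rowSums(sweep(points, 2, center)^2)) - r
  sphere(center, r, rms = sqrt(mean(res^2)))
}

#' Axis-seeded least-squares cylinder fit
#'
#' Minimizes the radial residuals sum((d_i - r)^2) where d_i is the distance
#' of each point to the axis; the radius is profiled out as mean(d_i).  The
#' axis direction is seeded with `init_axis` and refined by
#' Levenberg-Marquardt, so results are deterministic.
#'
#' @param points n x 3 matrix, n >= 6, spanning more than one axial position
#'   and a substantial arc.
#' @param init_axis initial guess for the axis direction.
#' @return A [cylinder] with the RMS radial residual.
#' @export
fit_cylinder <- function(points, init_axis) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("cylinder fit needs at least 6 points")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("degenerate cylinder fit: points are (near-)collinear")
  }
  if (sv[3] < 1e-12 * max(sv[1], 1) && sv[2] < 1e-12 * max(sv[1], 1)) {
    stop("degenerate cylinder fit: points span fewer than 3 directions")
  }
  d0 <- .unit3(init_axis)
  ctr <- colMeans(points)
  # parameters: axis direction as (theta, phi), axis point offsets (u, v)
  # in the plane orthogonal to the current direction
  th0 <- acos(min(1, max(-1, d0[3])))
  ph0 <- atan2(d0[2], d0[1])
  axis_frame <- function(d) {
    h <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- .unit3(.cross3(d, h))
    e2 <- .cross3(d, e1)
    list(e1 = e1, e2 = e2)
  }
  resid <- function(par) {
    th <- par[1]; ph <- par[2]
    d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    fr <- axis_frame(d)
    p0 <- ctr + par[3] * fr$e1 + par[4] * fr$e2
    rel <- sweep(points, 2, p0)
    proj <- rel %*% d
    perp <- rel - proj %*% t(d)
    di <- sqrt(rowSums(perp^2))
    di - mean(di)
  }
  fit <- minpack.lm::nls.lm(par = c(th0, ph0, 0, 0), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- fit$par
  d <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  fr <- axis_frame(d)
  p0 <- ctr + par[3] * fr$e1 + par[4] * fr$e2
  rel <- sweep(points, 2, p0)
  di <- sqrt(rowSums((rel - (rel %*% d) %*% t(d))^2))
  r <- mean(di)
  if (sum(d * .unit3(init_axis)) < 0) d <- -d  # canonical sign from the seed
  # place the axis point at the projection of the centroid onto the axis
  p0 <- p0 + as.numeric((ctr - p0) %*% d) * d
  cylinder(p0, d, r, rms = sqrt(mean((di - r)^2)))
}

#' Distance from a point to an infinite line
#'
#' The line extends through `a` and `b` without bound; the nearest point is
#' the orthogonal projection of `p` and may fall outside the segment ab.
#'
#' @param p,a,b length-3 points; `a` and `b` must be distinct.
#' @return List with `distance` and `nearest` (the projection of `p`).
#' @export
point_line_distance <- function(p, a, b) {
  u <- b - a
  n2 <- sum(u^2)
  if (n2 < 1e-24) stop("line is undefined: a and b coincide")
  t <- sum((p - a) * u) / n2
  nearest <- a + t * u
  list(distance = .norm3(p - nearest), nearest = nearest)
}

# ----------------------------------------------------------- meshes ------

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(!is.finite(vertices))) stop("mesh vertices must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      if (is_watertight(x)) "watertight" else "NOT watertight", "\n")
  invisible(x)
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).  Multi-component meshes pass if every component
#' is closed.
#'
#' @param mesh a [triangle_mesh].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  n <- nrow(mesh$vertices)
  directed <- (he_from - 1) * n + he_to
  if (anyDuplicated(directed) > 0L) return(FALSE)
  undirected <- (pmin(he_from, he_to) - 1) * n + pmax(he_from, he_to)
  all(tabulate(match(undirected, unique(undirected))) == 2L)
}

#' Apply a rigid transform to a mesh
#' @param mesh a [triangle_mesh].
#' @param transform a [rigid_transform].
#' @export
transform_mesh <- function(mesh, transform) {
  triangle_mesh(transform_points(transform, mesh$vertices), mesh$faces)
}

#' Do two watertight meshes interpenetrate?
#'
#' True iff any triangle pair intersects, or one mesh lies entirely inside
#' the other.  Surface contact within 1e-9 mm counts as interpenetration
#' (conservative viability).
#'
#' @param a,b watertight [triangle_mesh] objects.
#' @return Logical.
#' @export
meshes_interpenetrate <- function(a, b) {
  if (!is_watertight(a)) stop("mesh 'a' is not watertight")
  if (!is_watertight(b)) stop("mesh 'b' is not watertight")
  cpp_meshes_intersect(a$vertices, a$faces, b$vertices, b$faces)
}

#' Is a point inside a watertight mesh?
#' @param p length-3 point.
#' @param mesh a watertight [triangle_mesh].
#' @export
point_in_mesh <- function(p, mesh) {
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  cpp_point_in_mesh(as.numeric(p), mesh$vertices, mesh$faces)
}
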