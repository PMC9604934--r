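# Total-least-squares geometric fits and angle operations.
#
# Plane and line fits are orthogonal-distance (geometric) fits obtained from
# the eigen-decomposition of the point covariance; the sphere fit is an
# algebraic linear seed refined by Gauss-Newton on the geometric residuals
# ||p - c|| - r.  All fits are equivariant under rigid motions.  Direction
# signs are canonicalized here (first nonzero component positive); anatomical
# orientation is applied by the axis constructors, not here.

# sign canonicalization: first component larger than tol is made positive
.canonicalSign <- function(v, tol = 1e-12) {
  for (k in 1:3) {
    if (abs(v[k]) > tol) {
      if (v[k] < 0) v <- -v
      break
    }
  }
  v
}

.centeredEigen <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  list(center = ctr, values = ev$values, vectors = ev$vectors)
}

#' Orthogonal-distance (total least squares) plane fit
#'
#' Fits the plane through the centroid that minimizes the sum of squared
#' orthogonal distances to the points; the normal is the eigenvector of the
#' point covariance with the smallest eigenvalue.  The returned normal has a
#' canonical sign (first nonzero component positive); callers needing an
#' anatomical orientation re-orient it.
#'
#' @param points at least 3 non-collinear 3D points (n x 3 matrix, list of
#'   points, or flat vector).
#' @return A [Plane3-class] through the centroid.
#' @examples
#' fitPlane(cbind(runif(10), runif(10), 0))  # normal (0, 0, 1)
#' @export
fitPlane <- function(points) {
  pts <- .asPointMatrix(points, minRows = 3L)
  ev <- .centeredEigen(pts)
  scale <- max(ev$values[1L], .Machine$double.xmin)
  if (ev$values[2L] / scale < 1e-12)
    stop("degenerate geometry: points are collinear, no unique plane", call. = FALSE)
  new("Plane3", point = ev$center,
      normal = .canonicalSign(.unit(ev$vectors[, 3L])))
}

#' Orthogonal-distance line fit
#'
#' Fits the line through the centroid along the principal (maximal-variance)
#' direction of the points, minimizing summed squared orthogonal distances.
#' Direction sign is canonical; callers re-orient as needed.
#'
#' @param points at least 2 distinct 3D points.
#' @return An [Axis3-class] through the centroid.
#' @export
fitLine <- function(points) {
  pts <- .asPointMatrix(points, minRows = 2L)
  ev <- .centeredEigen(pts)
  if (ev$values[1L] <= 0 || sum(ev$values) < 1e-24)
    stop("degenerate geometry: all points coincide, no unique line", call. = FALSE)
  new("Axis3", point = ev$center,
      direction = .canonicalSign(.unit(ev$vectors[, 1L])))
}

#' Geometric least-squares sphere fit
#'
#' Algebraic (linear least squares) initialization followed by Gauss-Newton
#' refinement of the geometric objective `sum((||p - c|| - r)^2)`; iteration
#' stops when the parameter step falls below `tol` (mm).  The geometric
#' refinement matters for partial caps such as glenoid surfaces, where the
#' purely algebraic fit is biased.
#'
#' @param points at least 4 non-coplanar 3D points.
#' @param maxIter maximum Gauss-Newton iterations.
#' @param tol step-norm convergence tolerance in mm.
#' @return A [Sphere3-class].
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' pts <- cbind(5 * cos(th) + 1, 5 * sin(th) + 2, 3)
#' pts <- rbind(pts, c(1, 2, 8), c(1, 2, -2))
#' fitSphere(pts)  # center (1, 2, 3), radius 5
#' @export
fitSphere <- function(points, maxIter = 100L, tol = 1e-10) {
  pts <- .asPointMatrix(points, minRows = 4L)
  ev <- .centeredEigen(pts)
  scale <- max(ev$values[1L], .Machine$double.xmin)
  if (ev$values[3L] / scale < 1e-12)
    stop("degenerate geometry: points are coplanar, sphere fit is ill-posed",
         call. = FALSE)
  # algebraic seed: ||p||^2 = 2 p.c + (r^2 - ||c||^2), linear in (c, k)
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts * pts)
  sol <- qr.coef(qr(A), b)
  ctr <- sol[1:3]
  r <- sqrt(max(sol[4L] + sum(ctr * ctr), 1e-12))
  th <- c(ctr, r)
  for (it in seq_len(maxIter)) {
    d <- sweep(pts, 2L, th[1:3])
    dist <- sqrt(rowSums(d * d))
    if (any(dist < 1e-12)) break
    f <- dist - th[4L]
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.coef(qr(J), -f), error = function(e) rep(0, 4L))
    if (any(!is.finite(step))) break
    th <- th + step
    if (sqrt(sum(step * step)) < tol) break
  }
  if (!is.finite(th[4L]) || th[4L] <= 0)
    stop("sphere fit did not converge to a positive radius", call. = FALSE)
  new("Sphere3", center = as.numeric(th[1:3]), radius = as.numeric(th[4L]))
}

#' Project a direction onto a plane
#'
#' Removes the component of `direction` along the plane normal and
#' renormalizes.  Fails when the direction is parallel to the normal (within
#' 1e-6 rad), where the projection is undefined.
#'
#' @param direction a 3-vector (normalized internally).
#' @param plane a [Plane3-class].
#' @return A unit 3-vector lying in the plane.
#' @export
projectDirection <- function(direction, plane) {
  stopifnot(is(plane, "Plane3"))
  d <- .unit(as.numeric(direction))
  n <- plane@normal
  s <- d - sum(d * n) * n
  ns <- .norm3(s)
  if (ns < 1e-6)
    stop("undefined projection: direction is parallel to the plane normal",
         call. = FALSE)
  s / ns
}

#' Signed angle between two in-plane directions
#'
#' Angle from `u` to `v` in degrees, in (-180, 180], with the sign given by
#' the right-hand rule about `referenceNormal`.  Both vectors must lie in the
#' plane orthogonal to the reference normal (within 1e-6).
#'
#' @param u,v unit 3-vectors in the reference plane.
#' @param referenceNormal unit normal of the plane the angle is measured in.
#' @return Signed angle in degrees.
#' @examples
#' signedAngle(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))  # +90
#' @export
signedAngle <- function(u, v, referenceNormal) {
  u <- .unit(as.numeric(u))
  v <- .unit(as.numeric(v))
  n <- .unit(as.numeric(referenceNormal))
  if (abs(sum(u * n)) > 1e-6 || abs(sum(v * n)) > 1e-6)
    stop("signedAngle inputs must lie in the reference plane", call. = FALSE)
  ang <- atan2(sum(.cross(u, v) * n), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
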