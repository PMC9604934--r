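# Anatomical constructions: frontal plane, the three transverse axes, the
# glenoid mediolateral axis, the measurement frame, and the signed glenoid
# inclination.
#
# Sign convention (constructed explicitly because reported inclinations are
# conventionally positive for a superiorly tilted glenoid): the measurement
# frame carries an in-plane lateral direction (the projected transverse axis)
# and superior direction (projected inferior-angle -> glenoid-center,
# orthogonalized).  The frontal-plane normal is taken as lateral x superior
# ("anterior" by package convention), which makes the signed angle positive
# whenever the lateral glenoid direction has a positive component along
# superior.  Built from anatomy on both sides, the convention is
# laterality-invariant: a mirrored left scapula yields the same signed value.

# angle (degrees) between the projected transverse direction and the
# projected *lateral* glenoid direction, measured in the frame
.inclinationAngle <- function(transverseDir, glenoidMedialDir, frame) {
  pl <- frame@frontalPlane
  tLat <- projectDirection(transverseDir, pl)
  gLat <- projectDirection(-glenoidMedialDir, pl)
  signedAngle(tLat, gLat, pl@normal)
}

# estimate coarse anatomical directions from region centroids (used only to
# orient fitted normals/directions; never enters the angle magnitude)
.roughDirections <- function(mesh) {
  v <- mesh@vertices
  lab <- mesh@labels
  bodyC <- colMeans(v[lab == "body", , drop = FALSE])
  glenC <- colMeans(v[lab == "glenoid", , drop = FALSE])
  spineC <- colMeans(v[lab == "spine", , drop = FALSE])
  lat <- .unit(glenC - bodyC)
  supRaw <- spineC - bodyC
  sup <- supRaw - sum(supRaw * lat) * lat
  if (.norm3(sup) < 1e-9)
    stop("cannot orient mesh: spine and glenoid centroids are collinear with the body",
         call. = FALSE)
  list(lateral = lat, superior = .unit(sup))
}

#' Scapular frontal plane
#'
#' Orthogonal-distance plane fit to every vertex of the scapula except the
#' glenoid, acromion and coracoid (i.e. the body, spine and fossa regions).
#' The normal is oriented anteriorly: along `lateral x superior`, with
#' lateral and superior estimated from region centroids, so the orientation
#' follows the laterality encoded in the geometry.
#'
#' @param mesh a [ScapulaMesh-class].
#' @return A [Plane3-class].
#' @rdname frontalPlane
#' @export
setMethod("frontalPlane", "ScapulaMesh", function(mesh) {
  keep <- mesh@labels %in% c("body", "spine", "fossa")
  pl <- fitPlane(mesh@vertices[keep, , drop = FALSE])
  dirs <- .roughDirections(mesh)
  anterior <- .cross(dirs$lateral, dirs$superior)
  if (sum(pl@normal * anterior) < 0) pl@normal <- -pl@normal
  pl
})

#' Spine/body intersection points
#'
#' Every vertex that shares a triangle edge with a vertex of the other label,
#' for the `spine` and `body` regions; this label-based boundary stands in
#' for the geometric spine-root ridge.  Rows are ordered by ascending vertex
#' index, so the output is deterministic.
#'
#' @param mesh a [ScapulaMesh-class].
#' @return An n x 3 matrix of boundary vertex coordinates (mm).
#' @rdname spineBodyBoundary
#' @export
setMethod("spineBodyBoundary", "ScapulaMesh", function(mesh) {
  f <- mesh@faces
  lab <- mesh@labels
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  l1 <- lab[e[, 1L]]
  l2 <- lab[e[, 2L]]
  crossing <- (l1 == "spine" & l2 == "body") | (l1 == "body" & l2 == "spine")
  idx <- sort(unique(as.vector(e[crossing, , drop = FALSE])))
  if (!length(idx))
    stop("regions do not touch: no edge joins 'spine' and 'body'", call. = FALSE)
  mesh@vertices[idx, , drop = FALSE]
})

#' Y-axis transverse axis (fully automated)
#'
#' Best-fit line to the spine/body intersection points, translated to the
#' glenoid center and oriented to point laterally.  Uses only the mesh and a
#' glenoid center; no manual landmarks enter.
#'
#' @param mesh a [ScapulaMesh-class].
#' @param glenoidCenter numeric(3) glenoid center in mm.
#' @return An [Axis3-class] anchored at the glenoid center.
#' @rdname yAxis
#' @export
setMethod("yAxis", "ScapulaMesh", function(mesh, glenoidCenter) {
  stopifnot(.isPoint3(glenoidCenter))
  bpts <- spineBodyBoundary(mesh)
  ln <- fitLine(bpts)
  d <- ln@direction
  if (sum(d * (glenoidCenter - colMeans(bpts))) < 0) d <- -d
  new("Axis3", point = as.numeric(glenoidCenter), direction = d)
})

#' Glenoid center from apex landmarks
#'
#' Midpoint of the segment between the upper and lower glenoid apex.
#'
#' @param landmarks a [LandmarkSet-class].
#' @return numeric(3), mm.
#' @rdname glenoidCenter
#' @export
setMethod("glenoidCenter", "LandmarkSet", function(landmarks) {
  (landmarks@glenoidUpperApex + landmarks@glenoidLowerApex) / 2
})

#' Glenoid-trigonum transverse axis
#'
#' Line through the glenoid center and the trigonum, anchored at the center
#' and directed from the trigonum toward the center, i.e. laterally by
#' construction.
#'
#' @param glenoidCenter numeric(3), mm.
#' @param trigonum numeric(3), mm.
#' @return An [Axis3-class].
#' @export
gtLine <- function(glenoidCenter, trigonum) {
  stopifnot(.isPoint3(glenoidCenter), .isPoint3(trigonum))
  d <- glenoidCenter - trigonum
  if (.norm3(d) < 1e-12)
    stop("glenoid center and trigonum coincide", call. = FALSE)
  new("Axis3", point = as.numeric(glenoidCenter), direction = .unit(d))
}

#' Best-fit-line-fossa transverse axis
#'
#' Best-fit line to the five supraspinatus-fossa landmarks, anchored at the
#' glenoid center (the anchor does not affect the inclination; only the
#' direction enters) and oriented laterally.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param glenoidCenter numeric(3), mm.
#' @return An [Axis3-class].
#' @rdname bflfAxis
#' @export
setMethod("bflfAxis", "LandmarkSet", function(landmarks, glenoidCenter) {
  stopifnot(.isPoint3(glenoidCenter))
  ln <- fitLine(landmarks@fossaPoints)
  d <- ln@direction
  if (sum(d * (glenoidCenter - colMeans(landmarks@fossaPoints))) < 0) d <- -d
  new("Axis3", point = as.numeric(glenoidCenter), direction = d)
})

#' Glenoid mediolateral axis
#'
#' Fits a sphere to the glenoid-labeled vertices and returns the axis from
#' the glenoid center toward the sphere center.  The stored direction points
#' medially (into the bone); [inclination()] reverses it to compare
#' lateral-pointing representatives.
#'
#' @param mesh a [ScapulaMesh-class].
#' @param glenoidCenter numeric(3), mm.
#' @return An [Axis3-class] anchored at the glenoid center, pointing medially.
#' @rdname glenoidAxis
#' @export
setMethod("glenoidAxis", "ScapulaMesh", function(mesh, glenoidCenter) {
  stopifnot(.isPoint3(glenoidCenter))
  gl <- mesh@vertices[mesh@labels == "glenoid", , drop = FALSE]
  sph <- fitSphere(gl)
  d <- sph@center - glenoidCenter
  if (.norm3(d) < 1e-9)
    stop("glenoid center coincides with the best-fit sphere center", call. = FALSE)
  new("Axis3", point = as.numeric(glenoidCenter), direction = .unit(d))
})

# frame construction from a precomputed frontal plane (fast path for runStudy)
.frameFromPlane <- function(plane, transverseDir, inferiorAngle, glenoidCenter) {
  lat <- projectDirection(transverseDir, plane)
  supRaw <- projectDirection(.unit(glenoidCenter - inferiorAngle), plane)
  sup <- supRaw - sum(supRaw * lat) * lat
  if (.norm3(sup) < 1e-9)
    stop("degenerate frame: superior reference is parallel to the transverse axis",
         call. = FALSE)
  sup <- .unit(sup)
  plane@normal <- .cross(lat, sup)
  new("MeasurementFrame", frontalPlane = plane, superiorDir = sup, lateralDir = lat)
}

#' Measurement frame for signed inclination
#'
#' Builds the frontal plane from the mesh, takes the projected transverse
#' direction as the lateral axis, and the projection of the direction from
#' the inferior angle to the glenoid center - orthogonalized against lateral
#' - as the superior axis.  The plane normal is re-oriented to
#' `lateral x superior` (anterior convention) so the signed angle convention
#' is identical for left and right scapulae.
#'
#' @param mesh a [ScapulaMesh-class].
#' @param transverse the transverse [Axis3-class] (lateral-pointing).
#' @param inferiorAngle numeric(3), mm.
#' @param glenoidCenter numeric(3), mm.
#' @return A [MeasurementFrame-class].
#' @export
measurementFrame <- function(mesh, transverse, inferiorAngle, glenoidCenter) {
  stopifnot(is(mesh, "ScapulaMesh"), is(transverse, "Axis3"),
            .isPoint3(inferiorAngle), .isPoint3(glenoidCenter))
  .frameFromPlane(frontalPlane(mesh), transverse@direction, inferiorAngle,
                  glenoidCenter)
}

#' Signed glenoid inclination
#'
#' Projects the transverse axis and the glenoid mediolateral axis onto the
#' frontal plane (the glenoid axis is reversed to its lateral-pointing
#' representative first) and measures the signed angle between the projected
#' lines about the frame normal.  Positive values mean a superiorly tilted
#' glenoid.
#'
#' @param transverse transverse [Axis3-class], lateral-pointing.
#' @param glenoidMl glenoid mediolateral [Axis3-class], medial-pointing (as
#'   produced by [glenoidAxis()]).
#' @param frame a [MeasurementFrame-class].
#' @param method method tag stored in the result: `"y_axis"`, `"gt_line"` or
#'   `"bflf"`.
#' @return An [InclinationResult-class].
#' @export
inclination <- function(transverse, glenoidMl, frame, method = "y_axis") {
  stopifnot(is(transverse, "Axis3"), is(glenoidMl, "Axis3"),
            is(frame, "MeasurementFrame"))
  deg <- .inclinationAngle(transverse@direction, glenoidMl@direction, frame)
  new("InclinationResult", method = method, inclinationDeg = deg,
      transverseAxis = transverse, glenoidAxis = glenoidMl, frame = frame)
}

#' Measure glenoid inclination on a mesh + landmark set
#'
#' Convenience wrapper running the full construction: glenoid center (apex
#' midpoint), glenoid mediolateral axis (sphere fit), the requested
#' transverse axes, the per-method measurement frame, and the signed angle.
#' The same apex-midpoint glenoid center is shared by all three methods.
#'
#' @param mesh a [ScapulaMesh-class].
#' @param landmarks a [LandmarkSet-class].
#' @param methods subset of `c("y_axis", "gt_line", "bflf")`.
#' @return A single [InclinationResult-class] if one method is requested,
#'   otherwise a named list of them.
#' @examples
#' cs <- generateScapula(scapulaParams(trueInclinationDeg = 10))
#' res <- measureInclination(cs@mesh, cs@trueLandmarks)
#' vapply(res, inclinationDeg, numeric(1))  # all three close to 10
#' @export
measureInclination <- function(mesh, landmarks, methods = .METHODS) {
  stopifnot(is(mesh, "ScapulaMesh"), is(landmarks, "LandmarkSet"))
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  ctr <- glenoidCenter(landmarks)
  gAxis <- glenoidAxis(mesh, ctr)
  pl <- frontalPlane(mesh)
  out <- lapply(methods, function(m) {
    tr <- switch(m,
      y_axis = yAxis(mesh, ctr),
      gt_line = gtLine(ctr, landmarks@trigonum),
      bflf = bflfAxis(landmarks, ctr))
    fr <- .frameFromPlane(pl, tr@direction, landmarks@inferiorAngle, ctr)
    inclination(tr, gAxis, fr, method = m)
  })
  names(out) <- methods
  if (length(out) == 1L) out[[1L]] else out
}
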