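# S4 classes for the scapular measurement pipeline.
# Geometry primitives (Plane3, Axis3, Sphere3) are anatomy-agnostic; anatomical
# orientation conventions live in MeasurementFrame and the axis constructors.

# ---------------------------------------------------------------------------
# geometric primitives

#' Oriented plane in 3D
#'
#' A plane stored as an anchor point (mm) and a unit normal.  Produced by
#' [fitPlane()] and [frontalPlane()].
#'
#' @slot point numeric(3), a point on the plane, in mm.
#' @slot normal numeric(3), unit normal.
#' @export
setClass("Plane3", representation(point = "numeric", normal = "numeric"))

setValidity("Plane3", function(object) {
  if (!.isPoint3(object@point)) return("'point' must be a finite 3D point")
  if (!.isUnit3(object@normal)) return("'normal' must be a unit 3-vector (|norm - 1| <= 1e-9)")
  TRUE
})

#' Construct a Plane3
#'
#' @param point numeric(3) anchor point in mm.
#' @param normal numeric(3) normal vector; normalized if needed.
#' @return A [Plane3-class] object.
#' @export
Plane3 <- function(point, normal) {
  new("Plane3", point = as.numeric(point), normal = .unit(as.numeric(normal)))
}

#' Line (axis) in 3D
#'
#' An infinite oriented line stored as an anchor point (mm) and a unit
#' direction.  Used for every transverse-axis construction and for the glenoid
#' mediolateral axis.
#'
#' @slot point numeric(3), anchor point in mm.
#' @slot direction numeric(3), unit direction.
#' @export
setClass("Axis3", representation(point = "numeric", direction = "numeric"))

setValidity("Axis3", function(object) {
  if (!.isPoint3(object@point)) return("'point' must be a finite 3D point")
  if (!.isUnit3(object@direction)) return("'direction' must be a unit 3-vector (|norm - 1| <= 1e-9)")
  TRUE
})

#' Construct an Axis3
#'
#' @param point numeric(3) anchor point in mm.
#' @param direction numeric(3) direction vector; normalized if needed.
#' @return An [Axis3-class] object.
#' @export
Axis3 <- function(point, direction) {
  new("Axis3", point = as.numeric(point), direction = .unit(as.numeric(direction)))
}

#' Sphere in 3D
#'
#' @slot center numeric(3), center in mm.
#' @slot radius positive radius in mm.
#' @export
setClass("Sphere3", representation(center = "numeric", radius = "numeric"))

setValidity("Sphere3", function(object) {
  if (!.isPoint3(object@center)) return("'center' must be a finite 3D point")
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    return("'radius' must be a single positive number")
  TRUE
})

#' Construct a Sphere3
#'
#' @param center numeric(3) center in mm.
#' @param radius positive radius in mm.
#' @return A [Sphere3-class] object.
#' @export
Sphere3 <- function(center, radius) {
  new("Sphere3", center = as.numeric(center), radius = as.numeric(radius))
}

# ---------------------------------------------------------------------------
# domain containers

#' Labeled scapular surface mesh
#'
#' A triangle mesh of a segmented scapula with one anatomical region label per
#' vertex.  This is the output of upstream segmentation; the package never
#' touches CT data.  Regions `body`, `spine` and `glenoid` are mandatory
#' (they drive the frontal plane, the Y-axis and the glenoid axis);
#' `acromion`, `coracoid` and `fossa` may be empty.
#'
#' @slot vertices n x 3 numeric matrix of coordinates in mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot labels character vector, one region per vertex, values among
#'   `body`, `spine`, `glenoid`, `acromion`, `coracoid`, `fossa`.
#' @slot laterality `"right"` or `"left"`.
#' @seealso [readScapulaMesh()], [generateScapula()]
#' @export
setClass("ScapulaMesh",
  representation(vertices = "matrix", faces = "matrix",
                 labels = "character", laterality = "character"))

setValidity("ScapulaMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) return("'vertices' must be an n x 3 numeric matrix")
  if (!all(is.finite(v))) return("'vertices' contain non-finite coordinates")
  if (ncol(f) != 3L) return("'faces' must be an m x 3 index matrix")
  if (nrow(f) > 0L) {
    if (any(f != round(f))) return("'faces' must contain integer vertex indices")
    if (min(f) < 1L || max(f) > nrow(v)) return("face indices out of range")
  }
  if (length(object@labels) != nrow(v))
    return("every vertex must have exactly one label")
  bad <- setdiff(unique(object@labels), .REGIONS)
  if (length(bad))
    return(paste0("unknown region label(s): ", paste(bad, collapse = ", ")))
  for (reg in .MANDATORY_REGIONS) {
    if (!any(object@labels == reg))
      return(paste0("mandatory region '", reg, "' has no vertices"))
  }
  if (length(object@laterality) != 1L || !(object@laterality %in% .LATERALITIES))
    return("'laterality' must be \"right\" or \"left\"")
  TRUE
})

#' Construct a ScapulaMesh
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param labels character vector of per-vertex region labels.
#' @param laterality `"right"` (default) or `"left"`.
#' @return A validated [ScapulaMesh-class].
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1), c(2, 0, 0.5))
#' f <- rbind(c(1, 2, 3), c(2, 4, 3), c(2, 5, 4))
#' m <- ScapulaMesh(v, f, c("body", "body", "spine", "spine", "glenoid"))
#' @export
ScapulaMesh <- function(vertices, faces, labels, laterality = "right") {
  vertices <- .asPointMatrix(vertices, what = "vertices")
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  new("ScapulaMesh", vertices = vertices, faces = faces,
      labels = as.character(labels), laterality = laterality)
}

#' One rater's anatomical landmark picks
#'
#' The eight manually picked points of the measurement protocol: the trigonum
#' (spine / medial-border intersection), the upper and lower glenoid apexes
#' (their midpoint is the glenoid center), five points picked regularly along
#' the bottom of the supraspinatus fossa, and the inferior angle of the
#' scapula (used only to orient the superior direction of the measurement
#' frame).
#'
#' @slot trigonum numeric(3), mm.
#' @slot glenoidUpperApex numeric(3), mm.
#' @slot glenoidLowerApex numeric(3), mm.
#' @slot fossaPoints 5 x 3 numeric matrix, mm, ordered medial to lateral.
#' @slot inferiorAngle numeric(3), mm.
#' @slot raterId single character identifier.
#' @seealso [readLandmarks()], [simulateRater()]
#' @export
setClass("LandmarkSet",
  representation(trigonum = "numeric", glenoidUpperApex = "numeric",
                 glenoidLowerApex = "numeric", fossaPoints = "matrix",
                 inferiorAngle = "numeric", raterId = "character"))

setValidity("LandmarkSet", function(object) {
  for (nm in c("trigonum", "glenoidUpperApex", "glenoidLowerApex", "inferiorAngle")) {
    if (!.isPoint3(slot(object, nm)))
      return(paste0("'", nm, "' must be a finite 3D point"))
  }
  fp <- object@fossaPoints
  if (!is.numeric(fp) || nrow(fp) != 5L || ncol(fp) != 3L)
    return("fossa_points must have 5 entries (a 5 x 3 matrix)")
  if (!all(is.finite(fp))) return("'fossaPoints' contain non-finite coordinates")
  if (.norm3(object@glenoidUpperApex - object@glenoidLowerApex) == 0)
    return("glenoid upper and lower apex must be distinct")
  if (length(object@raterId) != 1L) return("'raterId' must be a single identifier")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param trigonum,glenoidUpperApex,glenoidLowerApex,inferiorAngle numeric(3)
#'   points in mm.
#' @param fossaPoints 5 x 3 matrix (or list of 5 points), mm.
#' @param raterId identifier of the rater, default `"unknown"`.
#' @return A validated [LandmarkSet-class].
#' @export
LandmarkSet <- function(trigonum, glenoidUpperApex, glenoidLowerApex,
                        fossaPoints, inferiorAngle, raterId = "unknown") {
  fp <- .asPointMatrix(fossaPoints, what = "fossa points")
  if (nrow(fp) != 5L) stop("fossa_points must have 5 entries", call. = FALSE)
  new("LandmarkSet",
      trigonum = as.numeric(trigonum),
      glenoidUpperApex = as.numeric(glenoidUpperApex),
      glenoidLowerApex = as.numeric(glenoidLowerApex),
      fossaPoints = fp,
      inferiorAngle = as.numeric(inferiorAngle),
      raterId = as.character(raterId))
}

#' Anatomical measurement frame in the scapular frontal plane
#'
#' Bundles the frontal plane with an orthonormal in-plane basis: the lateral
#' direction (projected transverse axis) and the superior direction (projected
#' inferior-angle-to-glenoid-center direction, orthogonalized against
#' lateral).  The stored plane normal equals `lateral x superior`, the
#' package's anterior convention, which makes the signed inclination positive
#' for a superiorly facing glenoid on either side.
#'
#' @slot frontalPlane a [Plane3-class].
#' @slot superiorDir unit numeric(3) in the frontal plane.
#' @slot lateralDir unit numeric(3) in the frontal plane.
#' @seealso [measurementFrame()]
#' @export
setClass("MeasurementFrame",
  representation(frontalPlane = "Plane3", superiorDir = "numeric",
                 lateralDir = "numeric"))

setValidity("MeasurementFrame", function(object) {
  n <- object@frontalPlane@normal
  s <- object@superiorDir
  l <- object@lateralDir
  if (!.isUnit3(s)) return("'superiorDir' must be a unit 3-vector")
  if (!.isUnit3(l)) return("'lateralDir' must be a unit 3-vector")
  if (abs(sum(s * n)) > 1e-9) return("superiorDir must be orthogonal to the frontal normal")
  if (abs(sum(l * n)) > 1e-9) return("lateralDir must be orthogonal to the frontal normal")
  if (abs(sum(s * l)) > 1e-9) return("superiorDir must be orthogonal to lateralDir")
  TRUE
})

#' Result of one inclination measurement
#'
#' Stores the signed inclination in degrees together with the constructions it
#' came from, so the angle can be re-derived from the stored axes and frame
#' (the validity method enforces agreement to 1e-6 degrees).
#'
#' @slot method one of `"y_axis"`, `"gt_line"`, `"bflf"`.
#' @slot inclinationDeg signed angle in degrees, in (-90, 90); positive means
#'   a superiorly tilted glenoid.
#' @slot transverseAxis the transverse [Axis3-class] used (lateral-pointing).
#' @slot glenoidAxis the glenoid mediolateral [Axis3-class] (medial-pointing,
#'   glenoid center toward sphere center).
#' @slot frame the [MeasurementFrame-class] the angle was measured in.
#' @export
setClass("InclinationResult",
  representation(method = "character", inclinationDeg = "numeric",
                 transverseAxis = "Axis3", glenoidAxis = "Axis3",
                 frame = "MeasurementFrame"))

setValidity("InclinationResult", function(object) {
  if (length(object@method) != 1L || !(object@method %in% .METHODS))
    return(paste0("'method' must be one of: ", paste(.METHODS, collapse = ", ")))
  a <- object@inclinationDeg
  if (length(a) != 1L || !is.finite(a)) return("'inclinationDeg' must be a finite scalar")
  if (a <= -90 || a >= 90) return("'inclinationDeg' must lie in (-90, 90)")
  recomputed <- .inclinationAngle(object@transverseAxis@direction,
                                  object@glenoidAxis@direction, object@frame)
  if (abs(recomputed - a) > 1e-6)
    return("stored inclination is inconsistent with the stored axes and frame")
  TRUE
})

# ---------------------------------------------------------------------------
# synthetic-scapula parameters

#' Parameters of the synthetic scapula generator
#'
#' See [generateScapula()] for the construction and [scapulaParams()] for
#' defaults and units.
#'
#' @slot trueInclinationDeg signed ground-truth inclination, degrees.
#' @slot bladeLength mediolateral blade extent, mm (also the
#'   trigonum-to-glenoid-center lever arm).
#' @slot bladeHeight superoinferior blade extent, mm.
#' @slot spineRootOffset width of the spine band above its root line, mm.
#' @slot glenoidRadius radius of the glenoid best-fit sphere, mm.
#' @slot glenoidCapAperture full cone angle of the glenoid spherical cap, degrees.
#' @slot trigonumOffsetSi superoinferior displacement of the true trigonum off
#'   the transverse axis, mm (medial-border morphology variants).
#' @slot meshResolution target edge length, mm.
#' @slot laterality `"right"` or `"left"`.
#' @export
setClass("ScapulaParams",
  representation(trueInclinationDeg = "numeric", bladeLength = "numeric",
                 bladeHeight = "numeric", spineRootOffset = "numeric",
                 glenoidRadius = "numeric", glenoidCapAperture = "numeric",
                 trigonumOffsetSi = "numeric", meshResolution = "numeric",
                 laterality = "character"))

setValidity("ScapulaParams", function(object) {
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@trueInclinationDeg)) return("'trueInclinationDeg' must be a finite scalar")
  if (abs(object@trueInclinationDeg) >= 60)
    return("'trueInclinationDeg' must lie in (-60, 60) degrees")
  if (!sc(object@bladeLength) || object@bladeLength <= 0) return("'bladeLength' must be > 0")
  if (!sc(object@bladeHeight) || object@bladeHeight <= 0) return("'bladeHeight' must be > 0")
  if (!sc(object@spineRootOffset) || object@spineRootOffset <= 0)
    return("'spineRootOffset' must be > 0")
  if (!sc(object@glenoidRadius) || object@glenoidRadius <= 0) return("'glenoidRadius' must be > 0")
  if (!sc(object@glenoidCapAperture) ||
      object@glenoidCapAperture <= 10 || object@glenoidCapAperture >= 120)
    return("'glenoidCapAperture' must lie in (10, 120) degrees")
  if (!sc(object@trigonumOffsetSi)) return("'trigonumOffsetSi' must be a finite scalar")
  if (!sc(object@meshResolution) || object@meshResolution <= 0)
    return("'meshResolution' must be > 0")
  if (length(object@laterality) != 1L || !(object@laterality %in% .LATERALITIES))
    return("'laterality' must be \"right\" or \"left\"")
  TRUE
})

#' Gaussian landmark-picking noise model for simulated raters
#'
#' Trigonum noise is anisotropic: picking disagreement concentrates along the
#' superoinferior axis, so `trigonumSdSi` (default 5 mm) exceeds
#' `trigonumSdOther` (default 2 mm).  Fossa and apex picks are isotropic.
#'
#' @slot trigonumSdSi SD of trigonum noise along the superior axis, mm.
#' @slot trigonumSdOther SD of trigonum noise in the two orthogonal directions, mm.
#' @slot fossaSd isotropic SD of each fossa pick, mm.
#' @slot apexSd isotropic SD of apex and inferior-angle picks, mm.
#' @slot nRaters number of simulated raters (>= 2).
#' @export
setClass("RaterNoiseModel",
  representation(trigonumSdSi = "numeric", trigonumSdOther = "numeric",
                 fossaSd = "numeric", apexSd = "numeric", nRaters = "integer"))

setValidity("RaterNoiseModel", function(object) {
  sds <- c(object@trigonumSdSi, object@trigonumSdOther, object@fossaSd, object@apexSd)
  if (length(sds) != 4L || any(!is.finite(sds)) || any(sds < 0))
    return("all noise SDs must be finite and >= 0")
  if (length(object@nRaters) != 1L || object@nRaters < 2L)
    return("'nRaters' must be >= 2")
  TRUE
})

#' A generated synthetic case with analytic ground truth
#'
#' @slot mesh the generated [ScapulaMesh-class].
#' @slot trueLandmarks the noise-free [LandmarkSet-class].
#' @slot truth named numeric(3): ground-truth inclination (degrees) for
#'   `y_axis`, `gt_line`, `bflf`.  `gt_line` differs from the other two when
#'   the trigonum is displaced off the transverse axis.
#' @slot params the [ScapulaParams-class] used.
#' @export
setClass("SyntheticCase",
  representation(mesh = "ScapulaMesh", trueLandmarks = "LandmarkSet",
                 truth = "numeric", params = "ScapulaParams"))

setValidity("SyntheticCase", function(object) {
  if (length(object@truth) != 3L || !all(.METHODS %in% names(object@truth)))
    return("'truth' must be a numeric(3) named y_axis, gt_line, bflf")
  if (!all(is.finite(object@truth))) return("'truth' must be finite")
  TRUE
})

# ---------------------------------------------------------------------------
# agreement statistics

#' Between-method agreement report
#'
#' Output of the staged concordance workflow: Pearson gate, Bland-Altman
#' bias/limits, and (only when a Bland-Altman threshold is exceeded) the Lin
#' concordance decomposition into lack of precision and lack of accuracy.
#' Fields of stages that were not reached are `NA`.
#'
#' @slot r Pearson correlation of the paired samples.
#' @slot biasDeg mean difference a - b, degrees.
#' @slot loaLowDeg,loaHighDeg 95% Bland-Altman limits of agreement, degrees.
#' @slot ccc Lin's concordance correlation coefficient.
#' @slot cB bias-correction (accuracy) factor, `ccc / r`.
#' @slot lopPct,loaPct percentage split of the total discordance `1 - ccc`
#'   into lack of precision and lack of accuracy; sums to 100.
#' @slot verdict one of `"concordant"`, `"discordant-precision-dominant"`,
#'   `"discordant-accuracy-dominant"`, `"correlation-failed"`.
#' @export
setClass("AgreementReport",
  representation(r = "numeric", biasDeg = "numeric", loaLowDeg = "numeric",
                 loaHighDeg = "numeric", ccc = "numeric", cB = "numeric",
                 lopPct = "numeric", loaPct = "numeric", verdict = "character"))

setValidity("AgreementReport", function(object) {
  v <- c("concordant", "discordant-precision-dominant",
         "discordant-accuracy-dominant", "correlation-failed")
  if (length(object@verdict) != 1L || !(object@verdict %in% v))
    return(paste0("'verdict' must be one of: ", paste(v, collapse = ", ")))
  r <- object@r
  if (!is.na(r) && (r < -1 - 1e-12 || r > 1 + 1e-12)) return("'r' must lie in [-1, 1]")
  if (!is.na(object@ccc)) {
    if (object@ccc > abs(r) + 1e-12) return("ccc must not exceed |r|")
    if (!is.na(object@cB) && (object@cB <= 0 || object@cB > 1 + 1e-12))
      return("c_b must lie in (0, 1]")
    if (!is.na(object@lopPct) && !is.na(object@loaPct) && object@ccc < 1 &&
        abs(object@lopPct + object@loaPct - 100) > 1e-9)
      return("LoP% + LoA% must equal 100")
  }
  if (!is.na(object@biasDeg) && !is.na(object@loaLowDeg) &&
      object@loaHighDeg - object@loaLowDeg > 1e-12 &&
      !(object@loaLowDeg < object@biasDeg && object@biasDeg < object@loaHighDeg))
    return("bias must lie strictly between the limits of agreement")
  TRUE
})

# ---------------------------------------------------------------------------
# study configuration / result

#' Configuration of a simulated multi-rater study
#'
#' Bundles the cohort design (number of cases and raters, ground-truth
#' inclination range, trigonum-offset mixture), the rater noise model, the
#' concordance thresholds and the output directory.  Defaults reproduce the
#' reference design: 82 cases, 4 raters, inclinations uniform on [-15, 21]
#' degrees, a 10% "worst-case" medial-border mixture, correlation gate 0.7,
#' bias threshold 3 degrees, limit-of-agreement half-width threshold 5
#' degrees, and a 5-degree discrepancy threshold.
#'
#' @slot nCases integer >= 2.
#' @slot seed integer RNG seed.
#' @slot inclinationRange numeric(2), degrees.
#' @slot offsetSdNormal SD (mm) of the typical trigonum SI offset.
#' @slot offsetSdWorst SD (mm) of the worst-case offset component.
#' @slot worstCaseProb mixture probability of a worst-case medial border.
#' @slot noise a [RaterNoiseModel-class].
#' @slot params template [ScapulaParams-class] (inclination/offset overwritten
#'   per case).
#' @slot rGate Pearson correlation gate.
#' @slot biasThreshold Bland-Altman bias threshold, degrees.
#' @slot ciThreshold Bland-Altman limit half-width threshold, degrees.
#' @slot outlierThreshold lone-outlier discrepancy threshold, degrees.
#' @slot outDir output directory (`character(0)` for none).
#' @export
setClass("StudyConfig",
  representation(nCases = "integer", seed = "integer",
                 inclinationRange = "numeric", offsetSdNormal = "numeric",
                 offsetSdWorst = "numeric", worstCaseProb = "numeric",
                 noise = "RaterNoiseModel", params = "ScapulaParams",
                 rGate = "numeric", biasThreshold = "numeric",
                 ciThreshold = "numeric", outlierThreshold = "numeric",
                 outDir = "character"))

setValidity("StudyConfig", function(object) {
  if (object@nCases < 2L) return("'nCases' must be >= 2")
  rng <- object@inclinationRange
  if (length(rng) != 2L || !all(is.finite(rng)) || rng[2L] < rng[1L])
    return("'inclinationRange' must be an ordered numeric(2)")
  if (object@worstCaseProb < 0 || object@worstCaseProb > 1)
    return("'worstCaseProb' must lie in [0, 1]")
  thr <- c(object@rGate, object@biasThreshold, object@ciThreshold, object@outlierThreshold)
  if (any(!is.finite(thr)) || any(thr <= 0)) return("thresholds must be positive")
  TRUE
})

#' Result of a simulated study
#'
#' @slot measurements data.frame with one row per (case, rater, method):
#'   columns `case`, `rater`, `method`, `inclination_deg`.
#' @slot raterAveraged data.frame of rater-averaged inclination per case and
#'   method (columns `case`, `truth_y_axis`..., `y_axis`, `gt_line`, `bflf`).
#' @slot summaryTable data.frame of Mean/Minimum/Maximum/SD per method.
#' @slot icc named list (per method) of ICC results.
#' @slot agreements named list (per method pair) of [AgreementReport-class].
#' @slot outliers list from [discrepancyOutliers()].
#' @slot failures integer vector of case indices that failed measurement.
#' @slot config the [StudyConfig-class] used.
#' @export
setClass("StudyResult",
  representation(measurements = "data.frame", raterAveraged = "data.frame",
                 summaryTable = "data.frame", icc = "list",
                 agreements = "list", outliers = "list",
                 failures = "integer", config = "StudyConfig"))

# ---------------------------------------------------------------------------
# show methods

setMethod("show", "Plane3", function(object) {
  cat("Plane3: point", .fmtPoint(object@point),
      "normal", .fmtPoint(object@normal), "\n")
})

setMethod("show", "Axis3", function(object) {
  cat("Axis3: point", .fmtPoint(object@point),
      "direction", .fmtPoint(object@direction), "\n")
})

setMethod("show", "Sphere3", function(object) {
  cat(sprintf("Sphere3: center %s radius %.2f mm\n",
              .fmtPoint(object@center), object@radius))
})

setMethod("show", "ScapulaMesh", function(object) {
  tab <- table(factor(object@labels, levels = .REGIONS))
  cat(sprintf("ScapulaMesh (%s): %d vertices, %d faces\n", object@laterality,
              nrow(object@vertices), nrow(object@faces)))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet [rater %s]\n", object@raterId))
  cat("  trigonum       ", .fmtPoint(object@trigonum), "\n")
  cat("  upper apex     ", .fmtPoint(object@glenoidUpperApex), "\n")
  cat("  lower apex     ", .fmtPoint(object@glenoidLowerApex), "\n")
  cat("  inferior angle ", .fmtPoint(object@inferiorAngle), "\n")
  cat("  fossa points   5\n")
})

setMethod("show", "InclinationResult", function(object) {
  cat(sprintf("InclinationResult [%s]: %.1f deg\n",
              object@method, object@inclinationDeg))
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport:", object@verdict, "\n")
  cat(sprintf("  r = %.3f", object@r))
  if (!is.na(object@biasDeg))
    cat(sprintf("; bias = %.1f deg, LoA [%.1f, %.1f]",
                object@biasDeg, object@loaLowDeg, object@loaHighDeg))
  cat("\n")
  if (!is.na(object@ccc))
    cat(sprintf("  CCC = %.2f, C_b = %.2f, LoP = %.0f%%, LoA = %.0f%%\n",
                object@ccc, object@cB, object@lopPct, object@loaPct))
})

setMethod("show", "SyntheticCase", function(object) {
  cat(sprintf("SyntheticCase: true inclination %.1f deg (%s)\n",
              object@params@trueInclinationDeg, object@mesh@laterality))
  cat(sprintf("  per-method truth: y_axis %.2f, gt_line %.2f, bflf %.2f deg\n",
              object@truth[["y_axis"]], object@truth[["gt_line"]],
              object@truth[["bflf"]]))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf("StudyConfig: %d cases x %d raters, seed %d\n",
              object@nCases, object@noise@nRaters, object@seed))
  cat(sprintf("  inclination range [%.1f, %.1f] deg, worst-case prob %.2f\n",
              object@inclinationRange[1L], object@inclinationRange[2L],
              object@worstCaseProb))
})

setMethod("show", "StudyResult", function(object) {
  cat(sprintf("StudyResult: %d cases measured (%d failed)\n",
              nrow(object@raterAveraged), length(object@failures)))
  print(object@summaryTable, digits = 3)
})
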