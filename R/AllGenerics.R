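# generics and simple accessors

#' @name accessors
#' @title Accessors for glenax S4 objects
#' @description Slot accessors for the core classes; use these rather than
#'   `@`.
#' @param x an object.
#' @return `vertices()` and `faces()` return matrices; `regionLabels()` a
#'   character vector; `laterality()` a string; `inclinationDeg()` a numeric
#'   scalar; `verdict()` a string; `measurements()` a data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' @rdname accessors
#' @export
setGeneric("inclinationDeg", function(x) standardGeneric("inclinationDeg"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))

#' @rdname accessors
#' @export
setMethod("vertices", "ScapulaMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("faces", "ScapulaMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setMethod("regionLabels", "ScapulaMesh", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("laterality", "ScapulaMesh", function(x) x@laterality)

#' @rdname accessors
#' @export
setMethod("inclinationDeg", "InclinationResult", function(x) x@inclinationDeg)

#' @rdname accessors
#' @export
setMethod("verdict", "AgreementReport", function(x) x@verdict)

#' @rdname accessors
#' @export
setMethod("measurements", "StudyResult", function(x) x@measurements)

#' @rdname frontalPlane
#' @export
setGeneric("frontalPlane", function(mesh) standardGeneric("frontalPlane"))

#' @rdname spineBodyBoundary
#' @export
setGeneric("spineBodyBoundary", function(mesh) standardGeneric("spineBodyBoundary"))

#' @rdname yAxis
#' @export
setGeneric("yAxis", function(mesh, glenoidCenter) standardGeneric("yAxis"))

#' @rdname glenoidAxis
#' @export
setGeneric("glenoidAxis", function(mesh, glenoidCenter) standardGeneric("glenoidAxis"))

#' @rdname glenoidCenter
#' @export
setGeneric("glenoidCenter", function(landmarks) standardGeneric("glenoidCenter"))

#' @rdname bflfAxis
#' @export
setGeneric("bflfAxis", function(landmarks, glenoidCenter) standardGeneric("bflfAxis"))
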