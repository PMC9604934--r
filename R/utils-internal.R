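# internal numeric helpers; all angles in radians here, degrees only at the API

.REGIONS <- c("body", "spine", "glenoid", "acromion", "coracoid", "fossa")
.MANDATORY_REGIONS <- c("body", "spine", "glenoid")
.LATERALITIES <- c("right", "left")
.METHODS <- c("y_axis", "gt_line", "bflf")

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-300) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.isPoint3 <- function(p) {
  is.numeric(p) && length(p) == 3L && all(is.finite(p))
}

.isUnit3 <- function(v, tol = 1e-9) {
  .isPoint3(v) && abs(.norm3(v) - 1) <= tol
}

# coerce anything point-like (vector, list of points, n x 3 matrix/data.frame)
# to an n x 3 numeric matrix
.asPointMatrix <- function(points, minRows = 1L, what = "points") {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3L, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) {
    stop(what, " must be 3D (an n x 3 matrix)", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop(what, " contain non-finite coordinates", call. = FALSE)
  }
  if (nrow(points) < minRows) {
    stop("need at least ", minRows, " ", what, ", got ", nrow(points), call. = FALSE)
  }
  points
}

# run code with a locally derived RNG state, restoring the caller's stream
.withLocalSeed <- function(seed, expr) {
  seed <- as.integer(seed %% 2147483647)
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.fmtPoint <- function(p) paste0("(", paste(sprintf("%.2f", p), collapse = ", "), ")")
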