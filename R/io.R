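# Readers and writers for labeled scapula meshes and landmark sets.
#
# PLY is the preferred mesh format: region labels travel as a per-vertex
# integer property `region` (codes 0=body 1=spine 2=glenoid 3=acromion
# 4=coracoid 5=fossa) and laterality as a header comment.  STL and OBJ carry
# no vertex attributes, so labels arrive through a sidecar CSV
# (`vertex_index,label`, 0-based indices).  Only ASCII variants are
# supported.  Coordinates are always millimetres; no unit autodetection.

.REGION_CODES <- stats::setNames(seq_along(.REGIONS) - 1L, .REGIONS)

.meshFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop("unsupported mesh format '", ext, "' (use PLY, STL or OBJ)", call. = FALSE)
  ext
}

.defaultSidecar <- function(path) paste0(tools::file_path_sans_ext(path), "_labels.csv")

.readLabelCsv <- function(path, nVertices) {
  if (!file.exists(path)) stop("label sidecar not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df)))
    stop("label CSV must have columns 'vertex_index' and 'label'", call. = FALSE)
  lab <- rep(NA_character_, nVertices)
  idx <- as.integer(df$vertex_index) + 1L  # 0-based on disk
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > nVertices))
    stop("label CSV vertex_index out of range", call. = FALSE)
  lab[idx] <- df$label
  if (anyNA(lab))
    stop("label CSV leaves ", sum(is.na(lab)), " vertices unlabeled", call. = FALSE)
  lab
}

# ---------------------------------------------------------------------------
# PLY

.readPlyAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("malformed PLY header (no end_header)", call. = FALSE)
  hdr <- trimws(lines[2:(endHdr - 1L)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L]))
    stop("only ASCII PLY is supported", call. = FALSE)

  laterality <- "right"
  latLine <- grep("^comment laterality ", hdr, value = TRUE)
  if (length(latLine)) laterality <- trimws(sub("^comment laterality ", "", latLine[1L]))

  # walk the header tracking the current element and its properties
  nVert <- nFace <- 0L
  vertProps <- character(0)
  current <- ""
  for (h in hdr) {
    tok <- strsplit(h, "[[:space:]]+")[[1L]]
    if (tok[1L] == "element") {
      current <- tok[2L]
      if (current == "vertex") nVert <- as.integer(tok[3L])
      if (current == "face") nFace <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && current == "vertex") {
      vertProps <- c(vertProps, tok[length(tok)])
    }
  }
  if (nVert < 1L) stop("PLY has no vertices", call. = FALSE)
  if (!all(c("x", "y", "z") %in% vertProps))
    stop("PLY vertex element must carry x, y, z properties", call. = FALSE)

  body <- lines[(endHdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nVert + nFace) stop("truncated PLY body", call. = FALSE)

  vertTok <- strsplit(trimws(body[seq_len(nVert)]), "[[:space:]]+")
  vmat <- matrix(as.numeric(unlist(vertTok)), nrow = nVert, byrow = TRUE)
  colnames(vmat) <- vertProps[seq_len(ncol(vmat))]
  verts <- vmat[, c("x", "y", "z"), drop = FALSE]
  dimnames(verts) <- NULL

  labels <- NULL
  if ("region" %in% colnames(vmat)) {
    codes <- as.integer(vmat[, "region"])
    if (any(is.na(codes)) || any(!(codes %in% .REGION_CODES)))
      stop("PLY 'region' property contains unknown region codes", call. = FALSE)
    labels <- names(.REGION_CODES)[codes + 1L]
  }

  faceMat <- matrix(integer(0), 0L, 3L)
  if (nFace > 0L) {
    faceTok <- strsplit(trimws(body[nVert + seq_len(nFace)]), "[[:space:]]+")
    faceMat <- t(vapply(faceTok, function(tk) {
      cnt <- as.integer(tk[1L])
      if (cnt != 3L) stop("only triangle faces are supported", call. = FALSE)
      as.integer(tk[2:4]) + 1L
    }, integer(3L)))
  }
  list(vertices = verts, faces = faceMat, labels = labels, laterality = laterality)
}

.writePlyAscii <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  codes <- .REGION_CODES[mesh@labels]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment labeled scapula surface (coordinates in mm)",
    paste("comment laterality", mesh@laterality),
    paste("comment region codes:",
          paste(sprintf("%d=%s", .REGION_CODES, names(.REGION_CODES)), collapse = " ")),
    paste("element vertex", nrow(v)),
    "property double x",
    "property double y",
    "property double z",
    "property int region",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g %d", v[, 1L], v[, 2L], v[, 3L], codes), con)
  if (nrow(f) > 0L)
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# OBJ / STL (geometry only; labels via sidecar CSV)

.readObj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vLines <- grep("^v[[:space:]]", lines, value = TRUE)
  fLines <- grep("^f[[:space:]]", lines, value = TRUE)
  if (!length(vLines)) stop("OBJ has no vertices", call. = FALSE)
  verts <- t(vapply(strsplit(trimws(vLines), "[[:space:]]+"),
                    function(tk) as.numeric(tk[2:4]), numeric(3L)))
  faceIdx <- function(tk) as.integer(vapply(strsplit(tk, "/", fixed = TRUE),
                                            `[`, character(1L), 1L))
  faceMat <- if (length(fLines)) {
    t(vapply(strsplit(trimws(fLines), "[[:space:]]+"), function(tk) {
      if (length(tk) != 4L) stop("only triangle faces are supported", call. = FALSE)
      faceIdx(tk[2:4])
    }, integer(3L)))
  } else matrix(integer(0), 0L, 3L)
  list(vertices = verts, faces = faceMat)
}

.writeObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# labeled scapula surface exported by glenax (mm)", con)
  v <- mesh@vertices
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  f <- mesh@faces
  if (nrow(f) > 0L) writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

.readStlAscii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^solid", lines[1L]))
    stop("only ASCII STL is supported", call. = FALSE)
  vLines <- grep("^vertex[[:space:]]", lines, value = TRUE)
  if (length(vLines) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3",
                                       call. = FALSE)
  coords <- t(vapply(strsplit(vLines, "[[:space:]]+"),
                     function(tk) as.numeric(tk[2:4]), numeric(3L)))
  # STL repeats vertices per facet; dedupe on the exact coordinate triple
  key <- apply(coords, 1L, paste, collapse = " ")
  uniq <- !duplicated(key)
  verts <- coords[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faceMat <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faceMat)
}

.writeStlAscii <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid scapula", con)
  for (k in seq_len(nrow(f))) {
    tri <- v[f[k, ], , drop = FALSE]
    n <- .cross(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
    nn <- .norm3(n)
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1L], n[2L], n[3L]),
                 "    outer loop",
                 sprintf("      vertex %.17g %.17g %.17g", tri[, 1L], tri[, 2L], tri[, 3L]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid scapula", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# public mesh API

#' Read a labeled scapula mesh
#'
#' Reads a triangle mesh from ASCII PLY, STL or OBJ and returns a validated
#' [ScapulaMesh-class].  PLY files written by [writeScapulaMesh()] embed the
#' region labels (per-vertex `region` property) and the laterality (header
#' comment); STL/OBJ need a sidecar label CSV with columns
#' `vertex_index` (0-based) and `label`.
#'
#' @param path mesh file path.
#' @param labels optional path to a label CSV (required for STL/OBJ; for PLY
#'   it overrides any embedded `region` property), or a character vector of
#'   per-vertex labels.
#' @param laterality optional override, `"right"` or `"left"`.
#' @return A [ScapulaMesh-class].
#' @seealso [writeScapulaMesh()]
#' @export
readScapulaMesh <- function(path, labels = NULL, laterality = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  fmt <- .meshFormat(path)
  raw <- switch(fmt,
    ply = .readPlyAscii(path),
    obj = .readObj(path),
    stl = .readStlAscii(path))
  lab <- raw$labels
  if (!is.null(labels)) {
    lab <- if (length(labels) == 1L && file.exists(labels) || (length(labels) == 1L && grepl("\\.csv$", labels)))
      .readLabelCsv(labels, nrow(raw$vertices))
    else as.character(labels)
  }
  if (is.null(lab)) {
    sidecar <- .defaultSidecar(path)
    if (file.exists(sidecar)) lab <- .readLabelCsv(sidecar, nrow(raw$vertices))
    else stop("mesh has unlabeled vertices: supply a label CSV via 'labels'",
              call. = FALSE)
  }
  lat <- if (!is.null(laterality)) laterality else raw$laterality
  if (is.null(lat)) lat <- "right"
  ScapulaMesh(raw$vertices, raw$faces, lab, lat)
}

#' Write a labeled scapula mesh
#'
#' Writes ASCII PLY (labels and laterality embedded), OBJ or STL (labels in a
#' sidecar CSV so they survive the attribute-free formats).  PLY round-trips
#' through [readScapulaMesh()] bit-for-bit.
#'
#' @param mesh a [ScapulaMesh-class].
#' @param path output path; the extension selects the format.
#' @param labelsPath sidecar CSV path for STL/OBJ (default:
#'   `<path>_labels.csv`); ignored for PLY.
#' @return `path`, invisibly.
#' @export
writeScapulaMesh <- function(mesh, path, labelsPath = NULL) {
  stopifnot(is(mesh, "ScapulaMesh"))
  fmt <- .meshFormat(path)
  if (fmt == "ply") return(invisible(.writePlyAscii(mesh, path)))
  if (fmt == "obj") .writeObj(mesh, path) else .writeStlAscii(mesh, path)
  if (is.null(labelsPath)) labelsPath <- .defaultSidecar(path)
  utils::write.csv(
    data.frame(vertex_index = seq_len(nrow(mesh@vertices)) - 1L,
               label = mesh@labels),
    labelsPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# landmarks

.landmarkNames <- c("trigonum", "glenoid_upper_apex", "glenoid_lower_apex",
                    "inferior_angle", paste0("fossa_", 1:5))

#' Read a landmark set
#'
#' JSON layout: `{"rater_id": ..., "trigonum": [x,y,z], "glenoid_upper_apex":
#' ..., "glenoid_lower_apex": ..., "fossa_points": [[x,y,z] x 5],
#' "inferior_angle": ...}`.  The CSV dialect is long format with columns
#' `landmark,x,y,z` (landmarks `trigonum`, `glenoid_upper_apex`,
#' `glenoid_lower_apex`, `inferior_angle`, `fossa_1` .. `fossa_5`) and an
#' optional `rater_id` column; both dialects produce identical objects.
#'
#' @param path JSON or CSV file.
#' @return A validated [LandmarkSet-class].
#' @seealso [writeLandmarks()]
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    need <- c("trigonum", "glenoid_upper_apex", "glenoid_lower_apex",
              "fossa_points", "inferior_angle")
    miss <- setdiff(need, names(obj))
    if (length(miss))
      stop("landmark JSON missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    fp <- .asPointMatrix(obj$fossa_points, what = "fossa points")
    if (nrow(fp) != 5L) stop("fossa_points must have 5 entries", call. = FALSE)
    LandmarkSet(obj$trigonum, obj$glenoid_upper_apex, obj$glenoid_lower_apex,
                fp, obj$inferior_angle,
                raterId = if (!is.null(obj$rater_id)) obj$rater_id else "unknown")
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("landmark", "x", "y", "z") %in% names(df)))
      stop("landmark CSV must have columns landmark, x, y, z", call. = FALSE)
    pt <- function(nm) {
      row <- df[df$landmark == nm, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("landmark CSV must contain exactly one '", nm, "' row", call. = FALSE)
      as.numeric(row[1L, c("x", "y", "z")])
    }
    nFossa <- sum(grepl("^fossa_", df$landmark))
    if (nFossa != 5L) stop("fossa_points must have 5 entries, found ", nFossa,
                           call. = FALSE)
    fp <- do.call(rbind, lapply(paste0("fossa_", 1:5), pt))
    rid <- if ("rater_id" %in% names(df)) as.character(df$rater_id[1L]) else "unknown"
    LandmarkSet(pt("trigonum"), pt("glenoid_upper_apex"), pt("glenoid_lower_apex"),
                fp, pt("inferior_angle"), raterId = rid)
  } else {
    stop("unsupported landmark format '", ext, "' (use JSON or CSV)", call. = FALSE)
  }
}

#' Write a landmark set
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output path; `.json` or `.csv` selects the dialect of
#'   [readLandmarks()].
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(rater_id = landmarks@raterId,
                trigonum = landmarks@trigonum,
                glenoid_upper_apex = landmarks@glenoidUpperApex,
                glenoid_lower_apex = landmarks@glenoidLowerApex,
                fossa_points = landmarks@fossaPoints,
                inferior_angle = landmarks@inferiorAngle)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    pts <- rbind(landmarks@trigonum, landmarks@glenoidUpperApex,
                 landmarks@glenoidLowerApex, landmarks@inferiorAngle,
                 landmarks@fossaPoints)
    utils::write.csv(
      data.frame(landmark = .landmarkNames, x = pts[, 1L], y = pts[, 2L],
                 z = pts[, 3L], rater_id = landmarks@raterId),
      path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported landmark format '", ext, "' (use JSON or CSV)", call. = FALSE)
  }
  invisible(path)
}
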