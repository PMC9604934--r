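# Parametric synthetic scapula with closed-form ground truth, plus the
# multi-rater landmark-noise simulator and cohort generation.
#
# Canonical right-scapula frame: lateral = +x, superior = +z, the blade in
# the y = 0 plane.  The blade is deliberately flat (zero curvature) so the
# frontal plane is exact and every ground-truth value is closed form;
# anatomical realism is traded for verifiability.  The spine root line and
# the fossa bottom line are both the x-axis, and the glenoid cap is placed
# so the apex midpoint (the glenoid center used by every method) sits exactly
# at the origin with the lateral glenoid direction making the requested
# inclination with +x.  With a zero trigonum offset all three transverse
# axes coincide with +x, so every method returns the true inclination
# exactly; a nonzero offset displaces the trigonum superoinferiorly and
# perturbs only the glenoid-trigonum method, by atan(offset / bladeLength).
# Left scapulae are the mirror image (x negated).

#' Construct synthetic-scapula parameters
#'
#' Defaults describe an average adult scapula: a 100 mm trigonum-to-glenoid
#' lever, 150 mm superoinferior blade extent (two thirds below the spine
#' root), a 10 mm spine band, a 30 mm glenoid best-fit sphere radius with a
#' 70 degree cap, and a 5 mm target edge length.
#'
#' @param trueInclinationDeg ground-truth signed inclination, degrees.
#' @param bladeLength mediolateral blade extent, mm.
#' @param bladeHeight superoinferior blade extent, mm.
#' @param spineRootOffset spine band width above the root line, mm.
#' @param glenoidRadius glenoid sphere radius, mm.
#' @param glenoidCapAperture full cone angle of the glenoid cap, degrees.
#' @param trigonumOffsetSi superoinferior trigonum displacement, mm.
#' @param meshResolution target edge length, mm.
#' @param laterality `"right"` or `"left"`.
#' @return A validated [ScapulaParams-class].
#' @export
scapulaParams <- function(trueInclinationDeg = 0, bladeLength = 100,
                          bladeHeight = 150, spineRootOffset = 10,
                          glenoidRadius = 30, glenoidCapAperture = 70,
                          trigonumOffsetSi = 0, meshResolution = 5,
                          laterality = "right") {
  new("ScapulaParams", trueInclinationDeg = trueInclinationDeg,
      bladeLength = bladeLength, bladeHeight = bladeHeight,
      spineRootOffset = spineRootOffset, glenoidRadius = glenoidRadius,
      glenoidCapAperture = glenoidCapAperture,
      trigonumOffsetSi = trigonumOffsetSi, meshResolution = meshResolution,
      laterality = laterality)
}

#' Construct a rater noise model
#'
#' Default magnitudes: trigonum 5 mm superoinferior / 2 mm otherwise (rater
#' disagreement on the trigonum concentrates along the superoinferior axis,
#' and 5 mm is the positioning-error scale the study design was powered on),
#' fossa picks 2 mm, apex and inferior-angle picks 1 mm, four raters.
#'
#' @param trigonumSdSi,trigonumSdOther,fossaSd,apexSd Gaussian SDs in mm.
#' @param nRaters number of raters, >= 2.
#' @return A validated [RaterNoiseModel-class].
#' @export
raterNoiseModel <- function(trigonumSdSi = 5, trigonumSdOther = 2,
                            fossaSd = 2, apexSd = 1, nRaters = 4L) {
  new("RaterNoiseModel", trigonumSdSi = trigonumSdSi,
      trigonumSdOther = trigonumSdOther, fossaSd = fossaSd, apexSd = apexSd,
      nRaters = as.integer(nRaters))
}

# triangulated rectangular grid in the y = 0 plane; returns vertices/faces
.gridPatch <- function(xs, zs) {
  nx <- length(xs)
  nz <- length(zs)
  verts <- cbind(rep(xs, times = nz), 0, rep(zs, each = nx))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nx - 1L)
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))
  list(vertices = verts, faces = faces)
}

#' Generate a synthetic scapula with analytic ground truth
#'
#' Builds a flat triangulated blade (regions `body`, `spine`, `fossa`
#' assigned by superoinferior position; the spine root line is the x-axis), a
#' glenoid spherical cap whose lateral axis makes exactly
#' `trueInclinationDeg` with +x in the frontal plane and whose apex midpoint
#' is the origin, small out-of-plane `acromion` and `coracoid` clusters
#' (excluded from the frontal plane by definition, so their offset exercises
#' the exclusion), and the noise-free landmark set: trigonum at the medial
#' end of the root displaced by `trigonumOffsetSi` along z, apexes at the cap
#' rim, five fossa points regularly spaced on the x-axis, and the inferior
#' angle at the bottom of the blade.  Left scapulae are generated by
#' mirroring x.  The construction is deterministic; `seed` is accepted for
#' interface symmetry and ignored.
#'
#' @param params a [ScapulaParams-class].
#' @param seed ignored (generation is deterministic).
#' @return A [SyntheticCase-class]; its `truth` slot holds the closed-form
#'   per-method inclination (`gt_line` includes the trigonum-offset term
#'   `atan(trigonumOffsetSi / bladeLength)`).
#' @examples
#' cs <- generateScapula(scapulaParams(trueInclinationDeg = 10))
#' cs@truth
#' @export
generateScapula <- function(params, seed = NULL) {
  stopifnot(is(params, "ScapulaParams"))
  L <- params@bladeLength
  res <- params@meshResolution
  hInf <- params@bladeHeight * 2 / 3
  hSup <- params@bladeHeight / 3
  alpha <- params@trueInclinationDeg * pi / 180
  rho <- params@glenoidCapAperture / 2 * pi / 180
  R <- params@glenoidRadius
  off <- params@trigonumOffsetSi
  if (abs(off) > hSup - 1e-9)
    stop("trigonumOffsetSi exceeds the blade extent above the spine root",
         call. = FALSE)
  if (res > R * rho)
    stop("mesh resolution too coarse to honor the glenoid cap aperture",
         call. = FALSE)

  # blade grid (x-rows include 0 exactly at z = 0 via construction of zs)
  xs <- seq(-L, 0, length.out = max(2L, round(L / res)) + 1L)
  zsBelow <- seq(-hInf, 0, length.out = max(1L, round(hInf / res)) + 1L)
  zsAbove <- seq(0, hSup, length.out = max(1L, round(hSup / res)) + 1L)[-1L]
  zs <- c(zsBelow, zsAbove)
  blade <- .gridPatch(xs, zs)
  zOfVert <- blade$vertices[, 3L]
  bladeLabels <- ifelse(zOfVert < 0, "body",
                 ifelse(zOfVert <= params@spineRootOffset + 1e-9, "spine", "fossa"))

  # glenoid cap: lateral glenoid direction g in the frontal plane
  g <- c(cos(alpha), 0, sin(alpha))
  u <- c(-sin(alpha), 0, cos(alpha))  # superior-ish, in-plane, orthogonal to g
  w <- c(0, 1, 0)
  M <- c(0, 0, 0)                      # apex midpoint = glenoid center
  C <- M - R * cos(rho) * g            # sphere center (medial of the center)
  nTheta <- max(2L, ceiling(R * rho / res))
  nPhi <- max(8L, 2L * ceiling(pi * R * sin(rho) / res))
  capVerts <- matrix(C + R * g, nrow = 1L)  # theta = 0 cap apex point
  thetas <- seq(0, rho, length.out = nTheta + 1L)[-1L]
  phis <- 2 * pi * (seq_len(nPhi) - 1L) / nPhi
  for (th in thetas) {
    ring <- t(vapply(phis, function(ph) {
      C + R * (cos(th) * g + sin(th) * (cos(ph) * u + sin(ph) * w))
    }, numeric(3L)))
    capVerts <- rbind(capVerts, ring)
  }
  ringStart <- function(k) 2L + (k - 1L) * nPhi  # first vertex of ring k
  capFaces <- NULL
  # fan apex -> ring 1
  r1 <- ringStart(1L) + seq_len(nPhi) - 1L
  capFaces <- cbind(1L, r1, c(r1[-1L], r1[1L]))
  if (nTheta > 1L) {
    for (k in seq_len(nTheta - 1L)) {
      a <- ringStart(k) + seq_len(nPhi) - 1L
      b <- ringStart(k + 1L) + seq_len(nPhi) - 1L
      a2 <- c(a[-1L], a[1L]); b2 <- c(b[-1L], b[1L])
      capFaces <- rbind(capFaces, cbind(a, b, b2), cbind(a, b2, a2))
    }
  }
  nBlade <- nrow(blade$vertices)
  capFaces <- capFaces + nBlade

  # acromion / coracoid: small out-of-plane clusters attached laterally
  topIdx <- which.min((blade$vertices[, 1L] - 0)^2 + (blade$vertices[, 3L] - hSup)^2)
  vTop <- blade$vertices[topIdx, ]
  acro <- rbind(vTop + c(-5, 10, 6), vTop + c(-14, 13, 4), vTop + c(-9, 16, 11))
  midIdx <- which.min((blade$vertices[, 1L] - 0)^2 + (blade$vertices[, 3L] - 10)^2)
  vMid <- blade$vertices[midIdx, ]
  cora <- rbind(vMid + c(-4, -11, 8), vMid + c(-10, -14, 12), vMid + c(-6, -9, 16))
  nCap <- nrow(capVerts)
  aBase <- nBlade + nCap
  extraFaces <- rbind(
    c(aBase + 1L, aBase + 2L, topIdx),
    c(aBase + 2L, aBase + 3L, topIdx),
    c(aBase + 4L, aBase + 5L, midIdx),
    c(aBase + 5L, aBase + 6L, midIdx))

  verts <- rbind(blade$vertices, capVerts, acro, cora)
  facesAll <- rbind(blade$faces, capFaces, extraFaces)
  labels <- c(bladeLabels, rep("glenoid", nCap),
              rep("acromion", 3L), rep("coracoid", 3L))

  # analytic landmarks
  trigonum <- c(-L, 0, off)
  upperApex <- C + R * (cos(rho) * g + sin(rho) * u)
  lowerApex <- C + R * (cos(rho) * g - sin(rho) * u)
  fossaX <- seq(-0.9 * L, -0.15 * L, length.out = 5L)
  fossaPts <- cbind(fossaX, 0, 0)
  infIdx <- which.min((blade$vertices[, 1L] + L / 2)^2 +
                      (blade$vertices[, 3L] + hInf)^2)
  inferiorAngle <- blade$vertices[infIdx, ]

  if (params@laterality == "left") {
    mir <- function(p) { p[1L] <- -p[1L]; p }
    verts[, 1L] <- -verts[, 1L]
    trigonum <- mir(trigonum)
    upperApex <- mir(upperApex)
    lowerApex <- mir(lowerApex)
    fossaPts[, 1L] <- -fossaPts[, 1L]
    inferiorAngle <- mir(inferiorAngle)
  }

  mesh <- ScapulaMesh(verts, facesAll, labels, params@laterality)
  lm <- LandmarkSet(trigonum, upperApex, lowerApex, fossaPts, inferiorAngle,
                    raterId = "truth")
  base <- params@trueInclinationDeg
  truth <- c(y_axis = base,
             gt_line = base + atan2(off, L) * 180 / pi,
             bflf = base)
  new("SyntheticCase", mesh = mesh, trueLandmarks = lm, truth = truth,
      params = params)
}

#' Simulate one rater's landmark picks
#'
#' Adds i.i.d. Gaussian noise to each landmark of a noise-free set.  The
#' trigonum is perturbed anisotropically: `trigonumSdSi` along
#' `superiorDir`, `trigonumSdOther` in the two orthogonal directions.  Fossa
#' points, apexes and the inferior angle are isotropic.  Deterministic given
#' `(seed, raterIndex)`; the caller's RNG stream is left untouched.
#'
#' @param truth a noise-free [LandmarkSet-class].
#' @param noise a [RaterNoiseModel-class].
#' @param raterIndex 1-based rater number (enters the derived seed).
#' @param seed integer seed.
#' @param superiorDir unit superoinferior direction of the case (default the
#'   canonical +z of [generateScapula()]).
#' @return A [LandmarkSet-class] with `raterId = "rater<k>"`.
#' @export
simulateRater <- function(truth, noise, raterIndex, seed,
                          superiorDir = c(0, 0, 1)) {
  stopifnot(is(truth, "LandmarkSet"), is(noise, "RaterNoiseModel"))
  s <- .unit(as.numeric(superiorDir))
  # orthonormal complement of s
  ref <- if (abs(s[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross(s, ref))
  e2 <- .cross(s, e1)
  .withLocalSeed(seed + 104729 * raterIndex, {
    trig <- truth@trigonum +
      stats::rnorm(1L, 0, noise@trigonumSdSi) * s +
      stats::rnorm(1L, 0, noise@trigonumSdOther) * e1 +
      stats::rnorm(1L, 0, noise@trigonumSdOther) * e2
    up <- truth@glenoidUpperApex + stats::rnorm(3L, 0, noise@apexSd)
    lo <- truth@glenoidLowerApex + stats::rnorm(3L, 0, noise@apexSd)
    fossa <- truth@fossaPoints +
      matrix(stats::rnorm(15L, 0, noise@fossaSd), 5L, 3L)
    inf <- truth@inferiorAngle + stats::rnorm(3L, 0, noise@apexSd)
    LandmarkSet(trig, up, lo, fossa, inf,
                raterId = paste0("rater", raterIndex))
  })
}

#' Generate a synthetic cohort with simulated raters
#'
#' Draws per-case ground-truth inclinations uniformly from
#' `inclinationRange` and trigonum superoinferior offsets from a two-
#' component Gaussian mixture: with probability `1 - worstCaseProb` a typical
#' medial border (`offsetSdNormal`), otherwise a "worst-case" morphology
#' (`offsetSdWorst`).  Each case is then observed by `noise@nRaters`
#' simulated raters.  Bit-reproducible given `seed`.
#'
#' @param nCases number of cases, >= 2.
#' @param inclinationRange numeric(2), degrees; default `c(-15, 21)` (the
#'   observed Y-axis range the generator emulates).
#' @param offsetSdNormal,offsetSdWorst mixture SDs in mm (defaults 2 and 10).
#' @param worstCaseProb mixture probability of the worst-case component
#'   (default 0.1, matching the roughly one-in-ten discordant-case rate the
#'   simulation emulates).
#' @param noise a [RaterNoiseModel-class].
#' @param seed integer seed.
#' @param params template [ScapulaParams-class]; its inclination, offset (and
#'   nothing else) are overwritten per case.
#' @return A list with elements `cases` (list of [SyntheticCase-class]),
#'   `raterLandmarks` (list of per-case lists of [LandmarkSet-class]) and
#'   `truth` (data.frame of per-case, per-method ground truth).
#' @export
generateCohort <- function(nCases, inclinationRange = c(-15, 21),
                           offsetSdNormal = 2, offsetSdWorst = 10,
                           worstCaseProb = 0.1,
                           noise = raterNoiseModel(), seed = 1L,
                           params = scapulaParams()) {
  stopifnot(nCases >= 2L, is(noise, "RaterNoiseModel"), is(params, "ScapulaParams"))
  if (length(inclinationRange) != 2L || inclinationRange[2L] < inclinationRange[1L])
    stop("invalid inclination range", call. = FALSE)
  draws <- .withLocalSeed(seed, {
    list(incl = stats::runif(nCases, inclinationRange[1L], inclinationRange[2L]),
         worst = stats::runif(nCases) < worstCaseProb,
         z = stats::rnorm(nCases))
  })
  offs <- draws$z * ifelse(draws$worst, offsetSdWorst, offsetSdNormal)
  maxOff <- params@bladeHeight / 3 - 1
  offs <- pmin(pmax(offs, -maxOff), maxOff)

  cases <- vector("list", nCases)
  raterLms <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    p <- params
    p@trueInclinationDeg <- draws$incl[i]
    p@trigonumOffsetSi <- offs[i]
    cs <- generateScapula(p)
    sup <- c(0, 0, 1)  # canonical generator frame
    cases[[i]] <- cs
    raterLms[[i]] <- lapply(seq_len(noise@nRaters), function(r) {
      simulateRater(cs@trueLandmarks, noise, r, seed = seed + 37L * i,
                    superiorDir = sup)
    })
  }
  truth <- data.frame(case = seq_len(nCases),
                      true_inclination_deg = draws$incl,
                      trigonum_offset_si = offs,
                      y_axis = vapply(cases, function(c) c@truth[["y_axis"]], 0),
                      gt_line = vapply(cases, function(c) c@truth[["gt_line"]], 0),
                      bflf = vapply(cases, function(c) c@truth[["bflf"]], 0))
  list(cases = cases, raterLandmarks = raterLms, truth = truth)
}
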