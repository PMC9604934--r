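# frontal plane, transverse axes, glenoid axis, frame, signed inclination

test_that("frontalPlane equals the definitional fit and is equivariant", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 5))
  m <- cs@mesh
  pl <- frontalPlane(m)
  # canonical blade lies in y = 0
  expect_equal(abs(pl@normal[2]), 1, tolerance = 1e-9)
  expect_equal(sum(pl@normal * pl@point), 0, tolerance = 1e-9)

  # definitional oracle: excluding glenoid/acromion/coracoid by hand
  keep <- regionLabels(m) %in% c("body", "spine", "fossa")
  direct <- fitPlane(vertices(m)[keep, , drop = FALSE])
  expect_lt(dirAngleDeg(pl@normal, direct@normal), 1e-9)
  expect_equal(pl@point, direct@point)

  # the exclusion matters: the out-of-plane regions would tilt the fit
  allFit <- fitPlane(vertices(m))
  expect_gt(dirAngleDeg(allFit@normal, direct@normal), 1e-4)

  R <- randomRotation(7)
  tc <- transformCase(m, cs@trueLandmarks, R, c(5, -3, 11))
  plR <- frontalPlane(tc$mesh)
  expect_lt(dirAngleDeg(plR@normal, as.numeric(R %*% pl@normal)), 1e-7)
})

test_that("spineBodyBoundary returns exactly the shared-edge vertices, in order", {
  m <- twoStripMesh()
  b <- spineBodyBoundary(m)
  # by hand: every body vertex (rows 1-4) shares a grid edge with a spine
  # vertex (rows 5-8) and vice versa; fossa and glenoid never qualify
  expect_identical(b, vertices(m)[1:8, ])

  # spine present but not touching body -> regions-do-not-touch failure
  v <- rbind(vertices(m), c(10, 0, 5), c(11, 0, 5), c(10.5, 0, 6))
  f <- rbind(faces(m), c(15, 16, 17))
  lab <- c(regionLabels(m), "spine", "spine", "spine")
  lab[5:8] <- "fossa"  # detach the old spine row
  m2 <- ScapulaMesh(v, f, lab)
  expect_error(spineBodyBoundary(m2), "do not touch")
})

test_that("yAxis runs along the spine root, anchored at the glenoid center", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 12))
  ctr <- glenoidCenter(cs@trueLandmarks)
  ax <- yAxis(cs@mesh, ctr)
  expect_equal(ax@point, ctr)
  expect_lt(dirAngleDeg(ax@direction, c(1, 0, 0)), 1e-9)
  expect_gt(ax@direction[1], 0)  # oriented laterally (+x on a right side)

  # noisy boundary agrees with the brute-force line fit on the same points
  set.seed(61)
  b <- spineBodyBoundary(cs@mesh)
  b <- b + matrix(rnorm(length(b), 0, 0.5), nrow(b), 3)
  expect_lt(dirAngleDeg(fitLine(b)@direction, oracleLineDirection(b)) * pi / 180,
            1e-6)
})

test_that("gtLine and bflfAxis build the manual transverse axes", {
  expect_equal(gtLine(c(0, 0, 0), c(-100, 0, 0))@direction, c(1, 0, 0))
  p <- c(5, 1, -2)
  expect_equal(gtLine(c(0, 0, 0) + p, c(-100, 0, 0) + p)@direction, c(1, 0, 0))
  expect_error(gtLine(c(1, 1, 1), c(1, 1, 1)), "coincide")
  # matches the generic 2-point line fit up to sign
  ln <- fitLine(rbind(c(-100, 0, 0), c(0, 0, 0)))
  expect_lt(dirAngleDeg(gtLine(c(0, 0, 0), c(-100, 0, 0))@direction,
                        ln@direction), 1e-12)

  d <- c(1, 0, 0.1) / sqrt(1.01)
  fossa <- (seq(-90, -20, length.out = 5) %o% d)
  lm <- LandmarkSet(c(-100, 0, 0), c(0, 1, 2), c(0, -1, -2), fossa, c(-50, 0, -90))
  ax <- bflfAxis(lm, c(0, 0, 0))
  expect_lt(dirAngleDeg(ax@direction, d), 1e-9)
  # order-free: permuting the five picks leaves the axis unchanged
  lmPerm <- LandmarkSet(lm@trigonum, lm@glenoidUpperApex, lm@glenoidLowerApex,
                        fossa[c(3, 1, 5, 2, 4), ], lm@inferiorAngle)
  expect_equal(bflfAxis(lmPerm, c(0, 0, 0))@direction, ax@direction)
  # noisy picks: same direction as the brute-force orthogonal fit
  set.seed(71)
  fn <- fossa + matrix(rnorm(15, 0, 1), 5, 3)
  lmN <- LandmarkSet(lm@trigonum, lm@glenoidUpperApex, lm@glenoidLowerApex,
                     fn, lm@inferiorAngle)
  expect_lt(dirAngleDeg(bflfAxis(lmN, c(0, 0, 0))@direction,
                        oracleLineDirection(fn)) * pi / 180, 1e-6)
})

test_that("glenoidAxis points from the center to the true sphere center", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 10))
  ctr <- glenoidCenter(cs@trueLandmarks)
  ax <- glenoidAxis(cs@mesh, ctr)
  alpha <- 10 * pi / 180
  gLat <- c(cos(alpha), 0, sin(alpha))
  expect_lt(dirAngleDeg(ax@direction, -gLat), 1e-6)  # stored medially

  # mirrored left-side case flips the mediolateral component
  csL <- generateScapula(scapulaParams(trueInclinationDeg = 10, laterality = "left"))
  axL <- glenoidAxis(csL@mesh, glenoidCenter(csL@trueLandmarks))
  expect_equal(axL@direction * c(-1, 1, 1), ax@direction, tolerance = 1e-6)

  # isotropic vertex noise moves the direction by well under half a degree
  set.seed(81)
  m <- cs@mesh
  noisy <- vertices(m)
  gi <- regionLabels(m) == "glenoid"
  noisy[gi, ] <- noisy[gi, ] + matrix(rnorm(3 * sum(gi), 0, 0.05), ncol = 3)
  mN <- ScapulaMesh(noisy, faces(m), regionLabels(m), laterality(m))
  expect_lt(dirAngleDeg(glenoidAxis(mN, ctr)@direction, ax@direction), 0.5)
})

test_that("measurementFrame is orthonormal and canonical on the generator", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 0))
  lm <- cs@trueLandmarks
  ctr <- glenoidCenter(lm)
  fr <- measurementFrame(cs@mesh, yAxis(cs@mesh, ctr), lm@inferiorAngle, ctr)
  expect_equal(fr@lateralDir, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr@superiorDir, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(sum(fr@superiorDir * fr@lateralDir), 0, tolerance = 1e-12)
  expect_equal(sum(fr@superiorDir * fr@frontalPlane@normal), 0, tolerance = 1e-12)
  expect_equal(sum(fr@lateralDir * fr@frontalPlane@normal), 0, tolerance = 1e-12)

  R <- randomRotation(17)
  tc <- transformCase(cs@mesh, lm, R, c(-4, 9, 2))
  ctrR <- glenoidCenter(tc$landmarks)
  frR <- measurementFrame(tc$mesh, yAxis(tc$mesh, ctrR),
                          tc$landmarks@inferiorAngle, ctrR)
  expect_equal(frR@lateralDir, as.numeric(R %*% fr@lateralDir), tolerance = 1e-7)
  expect_equal(frR@superiorDir, as.numeric(R %*% fr@superiorDir), tolerance = 1e-7)
})

test_that("inclination recovers generator truth with matched signs on both sides", {
  for (side in c("right", "left")) {
    cs <- generateScapula(scapulaParams(trueInclinationDeg = 10, laterality = side))
    vals <- inclinations3(cs@mesh, cs@trueLandmarks)
    expect_equal(unname(vals), rep(10, 3), tolerance = 1e-3)
  }
  # identical projections give zero
  cs0 <- generateScapula(scapulaParams())
  vals0 <- inclinations3(cs0@mesh, cs0@trueLandmarks)
  expect_equal(unname(vals0), rep(0, 3), tolerance = 1e-3)
  # result object is internally consistent
  res <- measureInclination(cs0@mesh, cs0@trueLandmarks, "y_axis")
  expect_s4_class(res, "InclinationResult")
  expect_true(validObject(res))
})

test_that("the full pipeline is rigid- and scale-invariant", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = -8, trigonumOffsetSi = 4))
  base <- inclinations3(cs@mesh, cs@trueLandmarks)
  for (s in 1:3) {
    R <- randomRotation(200 + s)
    tc <- transformCase(cs@mesh, cs@trueLandmarks, R, c(12, -5, 30) * s)
    expect_equal(inclinations3(tc$mesh, tc$landmarks), base, tolerance = 1e-6)
  }
  sc <- scaleCase(cs@mesh, cs@trueLandmarks, 2.5)
  expect_equal(inclinations3(sc$mesh, sc$landmarks), base, tolerance = 1e-6)
})

test_that("zero-noise methods agree pairwise and trigonum shifts hit only GT-line", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 6))
  vals <- inclinations3(cs@mesh, cs@trueLandmarks)
  expect_lt(max(vals) - min(vals), 1e-3)

  # superoinferior trigonum perturbation: GT monotone, Y-axis untouched
  lm <- cs@trueLandmarks
  deltas <- c(-10, -5, 0, 5, 10)
  gtv <- yv <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    lmd <- LandmarkSet(lm@trigonum + c(0, 0, deltas[i]), lm@glenoidUpperApex,
                       lm@glenoidLowerApex, lm@fossaPoints, lm@inferiorAngle)
    v <- inclinations3(cs@mesh, lmd)
    gtv[i] <- v[["gt_line"]]
    yv[i] <- v[["y_axis"]]
  }
  expect_true(all(diff(gtv) > 0))
  expect_equal(yv, rep(yv[1], length(yv)), tolerance = 1e-9)
})
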