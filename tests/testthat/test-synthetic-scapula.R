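# synthetic generator, rater simulator, cohort generation

test_that("ground truth is recovered across the inclination grid on both sides", {
  for (side in c("right", "left")) {
    for (alpha in seq(-20, 28, by = 8)) {
      cs <- generateScapula(scapulaParams(trueInclinationDeg = alpha,
                                          laterality = side))
      vals <- inclinations3(cs@mesh, cs@trueLandmarks)
      expect_equal(unname(vals), rep(alpha, 3), tolerance = 1e-3,
                   label = sprintf("side %s alpha %g", side, alpha))
      expect_equal(unname(cs@truth), rep(alpha, 3), tolerance = 1e-12)
    }
  }
})

test_that("a trigonum offset splits GT-line from Y-axis by arctan(offset/blade)", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 10,
                                      trigonumOffsetSi = 10, bladeLength = 100))
  vals <- inclinations3(cs@mesh, cs@trueLandmarks)
  expect_equal(vals[["y_axis"]], 10, tolerance = 1e-3)
  expect_equal(vals[["bflf"]], 10, tolerance = 1e-3)
  expect_equal(vals[["gt_line"]] - vals[["y_axis"]], atan(10 / 100) * 180 / pi,
               tolerance = 1e-3)
  expect_equal(cs@truth[["gt_line"]], 10 + atan(0.1) * 180 / pi, tolerance = 1e-9)
})

test_that("analytic landmarks lie on the generated surface", {
  p <- scapulaParams(trueInclinationDeg = 14, trigonumOffsetSi = 6)
  cs <- generateScapula(p)
  lm <- cs@trueLandmarks
  # blade landmarks: exactly in the blade plane, inside the blade rectangle
  for (pt in list(lm@trigonum, lm@inferiorAngle)) {
    expect_equal(pt[2], 0, tolerance = 1e-12)
    expect_true(pt[1] >= -p@bladeLength - 1e-9 && pt[1] <= 1e-9)
  }
  expect_true(all(abs(lm@fossaPoints[, 2]) < 1e-12))
  expect_true(all(abs(lm@fossaPoints[, 3]) < 1e-12))
  # apexes: exactly on the glenoid sphere and present among cap vertices
  sph <- fitSphere(vertices(cs@mesh)[regionLabels(cs@mesh) == "glenoid", ])
  for (apex in list(lm@glenoidUpperApex, lm@glenoidLowerApex)) {
    expect_equal(sqrt(sum((apex - sph@center)^2)), sph@radius, tolerance = 1e-6)
    d2 <- rowSums(sweep(vertices(cs@mesh), 2, apex)^2)
    expect_lt(min(d2), 1e-12)
  }
  # truth is recomputable from mesh + landmarks
  expect_equal(unname(inclinations3(cs@mesh, lm)), unname(cs@truth),
               tolerance = 1e-3)
})

test_that("generation is deterministic and rejects a too-coarse resolution", {
  p <- scapulaParams(trueInclinationDeg = 3)
  a <- generateScapula(p)
  b <- generateScapula(p)
  expect_identical(vertices(a@mesh), vertices(b@mesh))
  expect_identical(a@truth, b@truth)
  expect_error(generateScapula(scapulaParams(meshResolution = 40)), "coarse")
  expect_error(scapulaParams(glenoidCapAperture = 150), "glenoidCapAperture")
  expect_error(scapulaParams(glenoidRadius = -1), "glenoidRadius")
})

test_that("simulateRater is exact at zero noise and deterministic per seed", {
  cs <- generateScapula(scapulaParams(trueInclinationDeg = 5))
  lm <- cs@trueLandmarks
  none <- raterNoiseModel(0, 0, 0, 0)
  out <- simulateRater(lm, none, 1, seed = 42)
  expect_identical(out@trigonum, lm@trigonum)
  expect_identical(out@fossaPoints, lm@fossaPoints)
  expect_identical(out@glenoidUpperApex, lm@glenoidUpperApex)

  nm <- raterNoiseModel()
  a <- simulateRater(lm, nm, 2, seed = 42)
  b <- simulateRater(lm, nm, 2, seed = 42)
  expect_identical(a@trigonum, b@trigonum)
  expect_identical(a@fossaPoints, b@fossaPoints)
  # different rater index -> different draw
  c_ <- simulateRater(lm, nm, 3, seed = 42)
  expect_false(identical(a@trigonum, c_@trigonum))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateRater(lm, nm, 1, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated trigonum noise reproduces the anisotropic SDs", {
  cs <- generateScapula(scapulaParams())
  lm <- cs@trueLandmarks
  nm <- raterNoiseModel(trigonumSdSi = 5, trigonumSdOther = 2)
  n <- 10000
  picks <- vapply(seq_len(n),
                  function(k) simulateRater(lm, nm, k, seed = 7)@trigonum,
                  numeric(3))
  sds <- apply(picks - lm@trigonum, 1, sd)
  # superior axis is +z in the canonical frame; tolerances are relative (3%)
  expect_equal(sds[[3]], 5, tolerance = 0.03)
  expect_equal(sds[[1]], 2, tolerance = 0.03)
  expect_equal(sds[[2]], 2, tolerance = 0.03)
})

test_that("generateCohort has the right structure and is bit-reproducible", {
  ch <- generateCohort(5, noise = raterNoiseModel(nRaters = 4), seed = 3)
  expect_length(ch$cases, 5)
  expect_length(ch$raterLandmarks, 5)
  expect_true(all(vapply(ch$raterLandmarks, length, 0L) == 4))
  expect_s4_class(ch$cases[[1]], "SyntheticCase")
  expect_s4_class(ch$raterLandmarks[[3]][[2]], "LandmarkSet")

  ch2 <- generateCohort(5, noise = raterNoiseModel(nRaters = 4), seed = 3)
  expect_identical(ch$truth, ch2$truth)
  expect_identical(vertices(ch$cases[[2]]@mesh), vertices(ch2$cases[[2]]@mesh))
  expect_identical(ch$raterLandmarks[[4]][[1]]@trigonum,
                   ch2$raterLandmarks[[4]][[1]]@trigonum)

  # degenerate range pins every truth
  chDeg <- generateCohort(3, inclinationRange = c(5, 5), seed = 1)
  expect_equal(chDeg$truth$true_inclination_deg, rep(5, 3))
  expect_error(generateCohort(4, inclinationRange = c(10, -10)), "range")
})

test_that("cohort inclinations are uniform over the requested range", {
  # distribution check on the drawn truths (moderate n keeps generation cheap)
  ch <- generateCohort(400, inclinationRange = c(-15, 21), seed = 11,
                       noise = raterNoiseModel(nRaters = 2))
  x <- ch$truth$true_inclination_deg
  expect_true(all(x >= -15 & x <= 21))
  mid <- mean(c(-15, 21))
  se <- (21 - (-15)) / sqrt(12) / sqrt(400)
  expect_lt(abs(mean(x) - mid), 4 * se)
  # offset mixture: most cases typical, a minority widely displaced
  off <- ch$truth$trigonum_offset_si
  expect_gt(mean(abs(off) < 6), 0.8)
  expect_gt(sum(abs(off) > 6), 0)
})
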