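# programmatic fixtures: tiny labeled meshes and rigid-transformed cases

# 8-vertex mesh covering all six regions (two flat quads + two apex points)
tinyLabeledMesh <- function() {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 10), c(10, 0, 10),
             c(20, 0, 5), c(20, 2, 8), c(18, -2, 6), c(5, 0, 18))
  f <- rbind(c(1, 2, 3), c(2, 4, 3), c(2, 5, 4), c(5, 6, 4),
             c(5, 7, 2), c(4, 8, 3))
  ScapulaMesh(v, f,
              c("body", "body", "spine", "spine", "glenoid", "acromion",
                "coracoid", "fossa"))
}

# two-strip grid: 4 body vertices (z = -1 row), 4 spine (z = 0), 4 fossa
# (z = 1); the spine/body boundary is exactly the 8 vertices of the two
# lower rows (every z=0 vertex shares an edge with a z=-1 vertex and vice
# versa), enumerated by hand in the tests
twoStripMesh <- function() {
  xs <- c(0, 1, 2, 3)
  v <- rbind(cbind(xs, 0, -1), cbind(xs, 0, 0), cbind(xs, 0, 1),
             c(4, 0.5, 0), c(4, -0.5, 0.2))
  quad <- function(a, b, c_, d) rbind(c(a, b, d), c(a, d, c_))
  f <- NULL
  for (i in 1:3) {
    f <- rbind(f, quad(i, i + 1, i + 4, i + 5), quad(i + 4, i + 5, i + 8, i + 9))
  }
  f <- rbind(f, c(4, 13, 8), c(8, 14, 4))
  ScapulaMesh(v, f, c(rep("body", 4), rep("spine", 4), rep("fossa", 4),
                      "glenoid", "glenoid"))
}

# apply one rigid motion to a mesh and its landmark set
transformCase <- function(mesh, lm, R, t = c(0, 0, 0)) {
  tm <- ScapulaMesh(applyRigid(vertices(mesh), R, t), faces(mesh),
                    regionLabels(mesh), laterality(mesh))
  pt <- function(p) as.numeric(R %*% p + t)
  tl <- LandmarkSet(pt(lm@trigonum), pt(lm@glenoidUpperApex),
                    pt(lm@glenoidLowerApex), applyRigid(lm@fossaPoints, R, t),
                    pt(lm@inferiorAngle), lm@raterId)
  list(mesh = tm, landmarks = tl)
}

# uniformly scale a mesh + landmarks about the origin
scaleCase <- function(mesh, lm, s) {
  tm <- ScapulaMesh(vertices(mesh) * s, faces(mesh), regionLabels(mesh),
                    laterality(mesh))
  tl <- LandmarkSet(lm@trigonum * s, lm@glenoidUpperApex * s,
                    lm@glenoidLowerApex * s, lm@fossaPoints * s,
                    lm@inferiorAngle * s, lm@raterId)
  list(mesh = tm, landmarks = tl)
}

inclinations3 <- function(mesh, lm) {
  vapply(measureInclination(mesh, lm), inclinationDeg, numeric(1))
}
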