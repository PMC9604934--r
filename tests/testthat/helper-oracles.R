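# Independent brute-force oracles for the geometric fits and the ICC, plus
# rigid-transform helpers.  These never call the package's fitting code paths.

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

applyRigid <- function(points, R, t = c(0, 0, 0)) {
  sweep(points %*% t(R), 2L, t, `+`)
}

# direction from spherical angles
.dirFromAngles <- function(th) {
  c(sin(th[1L]) * cos(th[2L]), sin(th[1L]) * sin(th[2L]), cos(th[1L]))
}

# brute-force TLS plane: minimize sum of squared orthogonal distances over the
# normal direction (offset solved in closed form), multi-start Nelder-Mead
oraclePlaneNormal <- function(pts) {
  obj <- function(th) {
    n <- .dirFromAngles(th)
    d <- pts %*% n
    sum((d - mean(d))^2)
  }
  best <- NULL
  for (start in list(c(0.3, 0.3), c(1.2, 2.1), c(2.4, -1.0), c(1.57, 0.5))) {
    o <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  .dirFromAngles(best$par)
}

# brute-force TLS line: maximize variance along the direction
oracleLineDirection <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  obj <- function(th) {
    d <- .dirFromAngles(th)
    -sum((x %*% d)^2)
  }
  best <- NULL
  for (start in list(c(0.3, 0.3), c(1.2, 2.1), c(2.4, -1.0), c(1.57, 0.5))) {
    o <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  .dirFromAngles(best$par)
}

# brute-force geometric sphere fit over (center, radius)
oracleSphere <- function(pts) {
  ctr <- colMeans(pts)
  r0 <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(pts, 2L, p[1:3])^2))
    sum((d - p[4L])^2)
  }
  o <- optim(c(ctr, r0), obj, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 5000))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 20000))
  list(center = o$par[1:3], radius = o$par[4L])
}

# ICC(2,1) through stats::aov mean squares (independent of the package's
# direct sums-of-squares arithmetic)
oracleIcc21 <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   case = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(y ~ case + rater, data = df))[["Mean Sq"]]
  MSR <- ms[1L]; MSC <- ms[2L]; MSE <- ms[3L]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# smallest angle (degrees) between two directions, ignoring sign; atan2 of
# the cross/dot pair stays accurate for angles far below acos()'s resolution
dirAngleDeg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), abs(sum(u * v))) * 180 / pi
}
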