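# Independent oracles and fixture builders used across the suite.

# Pinhole camera written directly from K [R | t] (independent of
# make_camera_rig): returns the projection matrix and a projector.
pinhole_camera <- function(pos, lookat, focal_px = 3000,
                           image_size = c(1024, 1024), up = c(0, 0, 1)) {
  z <- lookat - pos; z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  K <- rbind(c(focal_px, 0, image_size[1] / 2),
             c(0, focal_px, image_size[2] / 2),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% pos)
  project <- function(p) {
    ph <- P %*% c(p, 1)
    c(ph[1] / ph[3], ph[2] / ph[3])
  }
  list(P = P, project = project,
       dlt = {Pn <- P / P[3, 4]; c(Pn[1, 1:4], Pn[2, 1:4], Pn[3, 1:3])},
       image_size = image_size)
}

# Euler-angle rotation used by the brute-force pose oracle.
rot_from_angles <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Brute-force rigid-pose fit: direct numerical minimization of the
# least-squares objective over Euler angles + translation.
brute_force_pose <- function(ref, obs) {
  obj <- function(par) {
    R <- rot_from_angles(par[1:3])
    fit <- sweep(ref %*% t(R), 2, par[4:6], `+`)
    sum((fit - obs)^2)
  }
  best <- NULL
  for (start in list(rep(0, 6), c(0.5, -0.5, 0.5, 0, 0, 0),
                     c(-1, 1, 2, 1, 1, 1))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(R = rot_from_angles(best$par[1:3]), t = best$par[4:6],
       value = best$value)
}

# Geodesic distance between two rotations (radians), via the Frobenius
# norm (||R1 - R2||_F = 2*sqrt(2)*sin(theta/2)), which stays accurate for
# tiny angles where acos(trace) loses precision.
rotation_angle <- function(R1, R2) {
  d <- sqrt(sum((R1 - R2)^2))
  2 * asin(min(1, d / (2 * sqrt(2))))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# Non-coplanar 26-point control object (two stacked offset grids plus two
# out-of-plane points), spanning the working volume.
control_object_26 <- function() {
  g <- expand.grid(x = c(-60, -20, 20, 60), y = c(-40, 0, 40), z = c(-30, 30))
  pts <- as.matrix(g)
  rbind(pts, c(0, 20, 0), c(10, -20, 10))
}

# Hand sum-of-squares one-way F statistic (oracle for anova_oneway).
brute_force_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Apply a rigid transform to a marker_traj3d.
transform_traj <- function(traj, R, tvec) {
  xyz <- as.matrix(traj[, c("X", "Y", "Z")])
  xyz2 <- sweep(xyz %*% t(R), 2, tvec, `+`)
  traj$X <- xyz2[, 1]; traj$Y <- xyz2[, 2]; traj$Z <- xyz2[, 3]
  traj
}

# Static trajectory helper.
static_traj <- function(marker, p, n, frame_rate = 500, noise_sd = 0) {
  xyz <- matrix(rep(p, each = n), n, 3)
  if (noise_sd > 0) xyz <- xyz + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  marker_traj3d(marker, xyz, frame_rate = frame_rate)
}
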