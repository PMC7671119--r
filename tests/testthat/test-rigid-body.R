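# Rigid-body pose fitting, body plane, precision metric, gap filling.

ref4 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 0), c(0, 0, 6))
def4 <- rigid_body_def("test", paste0("m", 1:4), ref4)

test_that("pose fitting recovers constructed transforms exactly", {
  # observed = reference: identity pose
  p0 <- fit_rigid_pose(def4, ref4)
  expect_lt(rotation_angle(p0$R, diag(3)), 1e-12)
  expect_lt(max(abs(p0$t)), 1e-12)
  expect_lt(p0$residual, 1e-12)

  # 90 degrees about Z then shift (1,2,3)
  Rz90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  obs <- sweep(ref4 %*% t(Rz90), 2, c(1, 2, 3), `+`)
  p1 <- fit_rigid_pose(def4, obs)
  expect_lt(rotation_angle(p1$R, Rz90), 1e-9)
  expect_equal(p1$t, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(p1$residual, 1e-9)
  expect_equal(det(p1$R), 1, tolerance = 1e-9)
})

test_that("SVD pose equals brute-force numerical minimization", {
  set.seed(11)
  for (i in 1:10) {
    R <- random_rotation()
    tv <- rnorm(3, 0, 20)
    obs <- sweep(ref4 %*% t(R), 2, tv, `+`) + matrix(rnorm(12, 0, 0.2), 4, 3)
    svd_fit <- fit_rigid_pose(def4, obs)
    bf <- brute_force_pose(ref4, obs)
    expect_lt(rotation_angle(svd_fit$R, bf$R), 1e-6)
    expect_lt(max(abs(svd_fit$t - bf$t)), 1e-6)
  }
})

test_that("noisy pose residuals follow the degrees-of-freedom scaling", {
  set.seed(21)
  sd <- 0.1
  res <- replicate(1000, {
    R <- random_rotation()
    obs <- sweep(ref4 %*% t(R), 2, rnorm(3), `+`) +
      matrix(rnorm(12, 0, sd), 4, 3)
    fit_rigid_pose(def4, obs)$residual
  })
  # per-coordinate RMS ~ sd * sqrt(1 - 6 / (3 * 4)): 6 pose dof from 12
  # coords; the reported residual is per-point RMS, i.e. sqrt(3) larger
  expect_equal(sqrt(mean(res^2)), sd * sqrt(3) * sqrt(1 - 6 / 12),
               tolerance = 0.05)
})

test_that("missing and degenerate frames are flagged, not fitted", {
  obs <- ref4; obs[c(1, 2), ] <- NA
  expect_true(fit_rigid_pose(def4, obs)$missing)
  # collinear visible markers
  refc <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  defc <- rigid_body_def("c", paste0("m", 1:4), refc)
  obsc <- refc; obsc[4, ] <- NA
  expect_true(fit_rigid_pose(defc, obsc)$degenerate)
  expect_error(rigid_body_def("bad", c("a", "b", "c"),
                              rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("pose fitting is equivariant under rigid motion of the scene", {
  set.seed(31)
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  traj <- truth$markers[truth$roles$neurocranium]
  pose <- fit_rigid_body(truth$defs$neurocranium, traj)
  R <- random_rotation(); tv <- c(100, -50, 30)
  pose2 <- fit_rigid_body(truth$defs$neurocranium,
                          lapply(traj, transform_traj, R = R, tvec = tv))
  for (f in c(1, 50, 101)) {
    expect_lt(rotation_angle(pose2$R[, , f], R %*% pose$R[, , f]), 1e-9)
    expect_lt(max(abs(pose2$t[f, ] -
                      (as.numeric(R %*% pose$t[f, ]) + tv))), 1e-9)
  }
})

test_that("body plane needs five markers and tracks rigid body motion", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  expect_error(fit_body_plane(rigid_body_def("p", paste0("m", 1:4), ref4),
                              truth$markers), ">= 5")
  pose <- fit_body_plane(truth$defs$body_plane, truth$markers)
  expect_false(any(pose$missing))
  expect_lt(max(pose$residual), 1e-9)

  # static body markers: constant pose
  static <- lapply(seq_len(5), function(i)
    static_traj(paste0("body_", i), truth$defs$body_plane$ref[i, ], 30))
  names(static) <- truth$defs$body_plane$markers
  ps <- fit_body_plane(truth$defs$body_plane, static)
  max_rot <- max(vapply(2:30, function(f)
    rotation_angle(ps$R[, , f], ps$R[, , f - 1]), numeric(1)))
  expect_lt(max_rot, 1e-9)
  expect_lt(max(abs(diff(ps$t))), 1e-9)
})

test_that("a mid-trial body translation is tracked exactly", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  def <- truth$defs$body_plane
  n <- 40
  shift <- c(rep(0, 20), rep(5, 20))
  traj <- lapply(seq_len(5), function(i) {
    xyz <- matrix(rep(def$ref[i, ], each = n), n, 3)
    xyz[, 1] <- xyz[, 1] + shift
    marker_traj3d(def$markers[i], xyz, frame_rate = 500)
  })
  names(traj) <- def$markers
  pose <- fit_body_plane(def, traj)
  expect_equal(pose$t[40, 1] - pose$t[1, 1], 5, tolerance = 1e-9)
  expect_lt(rotation_angle(pose$R[, , 1], pose$R[, , 40]), 1e-9)
})

test_that("pairwise-distance precision matches the analytic noise law", {
  set.seed(5)
  n <- 1e4
  sigma <- 0.1
  ta <- static_traj("a", c(0, 0, 0), n, noise_sd = sigma)
  tb <- static_traj("b", c(20, 0, 0), n, noise_sd = sigma)
  rep <- pairwise_distance_precision(list(a = ta, b = tb))
  se <- sigma * sqrt(2) / sqrt(2 * (n - 1))
  expect_lt(abs(rep$mean_sd - sigma * sqrt(2)), 3 * se)
  expect_identical(rep$n_pairs, 1L)
})

test_that("precision is zero for a noiseless rigid body and counts 6 pairs", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  rep <- pairwise_distance_precision(truth$markers[truth$roles$neurocranium])
  expect_identical(rep$n_pairs, 6L)  # 4 markers: 4*3/2
  expect_lt(rep$mean_sd, 1e-9)
  # invariant under rigid motion of the whole body
  R <- random_rotation()
  moved <- lapply(truth$markers[truth$roles$neurocranium],
                  transform_traj, R = R, tvec = c(5, 5, 5))
  rep2 <- pairwise_distance_precision(moved)
  expect_equal(rep2$pairs$mean_mm, rep$pairs$mean_mm, tolerance = 1e-9)
})

test_that("gap filling interpolates short interior gaps only", {
  n <- 60
  xyz <- cbind(seq(0, 59, 1), rep(2, n), rep(-1, n))  # linear motion
  tr <- marker_traj3d("m", xyz, frame_rate = 500)
  tr[25:27, c("X", "Y", "Z")] <- NA   # 3-frame gap
  tr[40:47, c("X", "Y", "Z")] <- NA   # 8-frame gap
  tr[1:2, c("X", "Y", "Z")] <- NA     # edge gap
  filled <- fill_gaps(tr, max_gap = 5)
  expect_equal(filled$X[25:27], c(24, 25, 26), tolerance = 1e-9)
  expect_true(all(filled$filled[25:27]))
  expect_true(all(is.na(filled$X[40:47])))  # too long
  expect_true(all(is.na(filled$X[1:2])))    # edge gap stays
  expect_identical(fill_gaps(tr, max_gap = 0), tr)
})
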