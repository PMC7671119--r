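# ACS excursions, JCS elevation, peak-gape detection, trial summaries.

# A trivial static body pose series: identity rotation, zero translation.
identity_pose <- function(n, frame_rate = 500, id = "body") {
  structure(list(id = id,
                 R = array(diag(3), c(3, 3, n)),
                 t = matrix(0, n, 3),
                 residual = rep(0, n), n_markers = rep(5L, n),
                 missing = rep(FALSE, n), degenerate = rep(FALSE, n),
                 frame_rate = frame_rate, n_frames = n),
            class = "rigid_body_pose")
}

test_that("excursion signs follow the retraction/depression convention", {
  n <- 40
  pose <- identity_pose(n)
  xyz <- matrix(rep(c(10, 0, -5), each = n), n, 3)
  xyz[30:40, 1] <- 10 - 2   # caudal move: -X
  xyz[30:40, 3] <- -5 - 3   # ventral move: -Z
  tr <- marker_traj3d("uro", xyz, frame_rate = 500)
  exc <- acs_excursions(pose, tr, baseline = 1:20)
  expect_equal(max(exc$retraction), 2, tolerance = 1e-12)
  expect_equal(max(exc$depression), 3, tolerance = 1e-12)
  # baseline zeroing is exact by construction
  expect_equal(mean(exc$retraction[1:20]), 0, tolerance = 1e-12)
  expect_equal(mean(exc$depression[1:20]), 0, tolerance = 1e-12)
})

test_that("body-plane parenting removes whole-body motion", {
  # fish swims through the tank; marker rigidly attached to the body
  truth <- simulate_strike(strike_params(
    elevation_amp = 0, urohyal_retraction_amp = 0, urohyal_depression_amp = 0,
    cleithrum_retraction_amp = 0, cleithrum_depression_amp = 0,
    gape_amp = 0, sh_peak_strain = 0, epax_peak_strain = 0,
    swim_speed = 80, yaw_amp = 3, pixel_noise_sd = 0))
  pose <- fit_body_plane(truth$defs$body_plane, truth$markers)
  exc <- acs_excursions(pose, truth$markers$urohyal, baseline = 1:20)
  expect_lt(max(abs(exc$retraction)), 1e-9)
  expect_lt(max(abs(exc$depression)), 1e-9)
})

test_that("generator excursion amplitudes are recovered through the ACS", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  pose <- fit_body_plane(truth$defs$body_plane, truth$markers)
  uro <- acs_excursions(pose, truth$markers$urohyal, baseline = 1:20)
  cl <- acs_excursions(pose, truth$markers$cleithrum, baseline = 1:20)
  p <- truth$params
  expect_equal(max(uro$retraction), p$urohyal_retraction_amp, tolerance = 1e-6)
  expect_equal(max(uro$depression), p$urohyal_depression_amp, tolerance = 1e-6)
  expect_equal(max(cl$retraction), p$cleithrum_retraction_amp, tolerance = 1e-6)
  expect_equal(max(cl$depression), p$cleithrum_depression_amp, tolerance = 1e-6)
})

test_that("JCS elevation recovers constructed and simulated pitches", {
  n <- 40
  body <- identity_pose(n)
  neuro <- identity_pose(n, id = "neuro")
  # identity all frames: elevation identically zero
  e0 <- jcs_elevation(body, neuro, baseline = 1:10)
  expect_true(all(abs(e0$elevation) < 1e-12))
  # pure +10 degree rotation about the ACS Y axis after frame 20
  Ry10 <- rbind(c(cos(pi / 18), 0, sin(pi / 18)), c(0, 1, 0),
                c(-sin(pi / 18), 0, cos(pi / 18)))
  for (f in 21:40) neuro$R[, , f] <- Ry10
  e1 <- jcs_elevation(body, neuro, baseline = 1:10)
  expect_equal(e1$elevation[40], 10, tolerance = 1e-9)

  # generator closure: peak elevation equals the generator amplitude
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  bp <- fit_body_plane(truth$defs$body_plane, truth$markers)
  np <- fit_rigid_body(truth$defs$neurocranium, truth$markers)
  es <- jcs_elevation(bp, np, baseline = 1:20)
  expect_equal(max(es$elevation), truth$params$elevation_amp, tolerance = 1e-6)
  expect_equal(es$elevation, truth$kinematics$elevation, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pure Y rotations decompose with zero Z and X angles", {
  for (ang in c(-1.2, -0.3, 0.4, 1.1)) {
    R <- rbind(c(cos(ang), 0, sin(ang)), c(0, 1, 0),
               c(-sin(ang), 0, cos(ang)))
    e <- vromm:::euler_zyx(R)
    expect_equal(e[2], ang, tolerance = 1e-12)
    expect_lt(abs(e[1]), 1e-12)
    expect_lt(abs(e[3]), 1e-12)
  }
})

test_that("kinematics are invariant under rigid motion of the whole scene", {
  set.seed(13)
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  R <- random_rotation(); tv <- c(-30, 70, 15)
  moved <- lapply(truth$markers, transform_traj, R = R, tvec = tv)
  run <- function(markers) {
    bp <- fit_body_plane(truth$defs$body_plane, markers)
    np <- fit_rigid_body(truth$defs$neurocranium, markers)
    list(exc = acs_excursions(bp, markers$urohyal, 1:20),
         elev = jcs_elevation(bp, np, 1:20))
  }
  a <- run(truth$markers); b <- run(moved)
  expect_lt(max(abs(a$exc$retraction - b$exc$retraction)), 1e-9)
  expect_lt(max(abs(a$exc$depression - b$exc$depression)), 1e-9)
  expect_lt(max(abs(a$elev$elevation - b$elev$elevation)), 1e-9)
})

test_that("peak gape detection honours the earliest-tie rule and smoothing", {
  g <- c(rep(1, 49), 2, rep(1, 50))
  expect_identical(detect_peak_gape(g, 500, smooth_window = 1)$frame, 50L)
  plateau <- c(rep(1, 49), 3, 3, 3, rep(1, 48))
  expect_identical(detect_peak_gape(plateau, 500, smooth_window = 1)$frame, 50L)
  expect_error(detect_peak_gape(c(NA, NA, 1), 500), "finite")

  # noisy unimodal pulse: detected within 2 frames of truth in >= 95% of runs
  set.seed(99)
  t <- (0:100) / 500
  gape <- 4 + 8 * vromm:::raised_cosine(t, 0.1, 0.06)
  hits <- replicate(500, {
    noisy <- gape + rnorm(101, 0, 0.01 * diff(range(gape)))
    abs(detect_peak_gape(noisy, 500, smooth_window = 5)$frame - 51) <= 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("trial summaries report peaks and event-relative latencies", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  bp <- fit_body_plane(truth$defs$body_plane, truth$markers)
  np <- fit_rigid_body(truth$defs$neurocranium, truth$markers)
  exc <- lapply(truth$roles$excursion_markers, function(m)
    acs_excursions(bp, truth$markers[[m]], 1:20))
  elev <- jcs_elevation(bp, np, 1:20)
  s <- summarize_trial(exc, elev, truth$events, truth$params$frame_rate)
  expect_equal(s$peak[s$variable == "urohyal_depression"], 3, tolerance = 1e-6)
  expect_equal(s$latency_ms[s$variable == "elevation"], 0, tolerance = 1e-9)

  # a peak 16 ms after peak gape reports +16
  n <- 101
  exc1 <- exc[1]
  exc1$urohyal$retraction <- vromm:::raised_cosine((0:100) / 500, 0.116, 0.06)
  s2 <- summarize_trial(exc1, NULL, truth$events, 500)
  expect_equal(s2$latency_ms[s2$variable == "urohyal_retraction"], 16)
})
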