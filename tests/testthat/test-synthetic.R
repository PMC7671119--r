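# Synthetic strike generator, camera rig and renderer.

test_that("parameter validation names the offending field", {
  expect_s3_class(strike_params(), "strike_params")
  expect_error(strike_params(elevation_amp = -1), "elevation_amp")
  expect_error(strike_params(frame_rate = 0), "frame_rate")
  expect_error(strike_params(t_peak_gape = 0.3, duration = 0.2), "t_peak_gape")
  expect_error(strike_params(skin_slip_alpha = 0), "skin_slip_alpha")
  expect_error(strike_params(skin_slip_alpha = 1.2), "skin_slip_alpha")
  expect_error(strike_params(L_i_sh = NaN), "L_i_sh")
})

test_that("external muscle length follows the skin-slip construction", {
  truth <- simulate_strike(strike_params(sh_peak_strain = 7.2, L_i_sh = 10,
                                         skin_slip_alpha = 1,
                                         pixel_noise_sd = 0))
  # elementwise: L_ext = L_i * (1 - alpha * s_int / 100)
  expect_equal(truth$strain$sh_length_external,
               10 * (1 - truth$strain$sh_internal / 100), tolerance = 1e-12)
  expect_equal(min(truth$strain$sh_length_external), 9.28, tolerance = 1e-3)
  # and the rendered marker pair reproduces it exactly
  len <- muscle_length(truth$markers$urohyal, truth$markers$sh_caudal)
  expect_equal(len, truth$strain$sh_length_external, tolerance = 1e-9)
})

test_that("an all-zero-amplitude strike is perfectly static", {
  truth <- simulate_strike(strike_params(
    elevation_amp = 0, urohyal_retraction_amp = 0, urohyal_depression_amp = 0,
    cleithrum_retraction_amp = 0, cleithrum_depression_amp = 0, gape_amp = 0,
    sh_peak_strain = 0, epax_peak_strain = 0, swim_speed = 0, yaw_amp = 0,
    pixel_noise_sd = 0))
  for (m in names(truth$markers)) {
    xyz <- as.matrix(truth$markers[[m]][, c("X", "Y", "Z")])
    expect_lt(max(abs(sweep(xyz, 2, xyz[1, ]))), 1e-12)
  }
  expect_true(all(truth$strain$sh_internal == 0))
  expect_true(all(truth$strain$epax_internal == 0))
})

test_that("within-body pairwise distances are conserved to numerical precision", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  for (body in list(truth$roles$neurocranium, truth$roles$body_plane)) {
    pr <- pairwise_distance_precision(truth$markers[body])
    expect_lt(pr$mean_sd, 1e-9)
  }
})

test_that("the jaw-marker distance peaks exactly at peak gape", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  gape <- muscle_length(truth$markers$jaw_upper, truth$markers$jaw_lower)
  expect_identical(which.max(gape),
                   as.integer(truth$events$frame[1]))
  expect_equal(gape, truth$gape, tolerance = 1e-9)
})

test_that("simulation and rendering are deterministic given a seed", {
  p <- strike_params(seed = 42)
  t1 <- simulate_strike(p); t2 <- simulate_strike(p)
  expect_identical(t1, t2)
  rig <- make_camera_rig(3)
  o1 <- render_observations(t1, rig, seed = 42)
  o2 <- render_observations(t2, rig, seed = 42)
  expect_identical(o1, o2)
  o3 <- render_observations(t1, rig, seed = 43)
  expect_false(identical(o1, o3))
})

test_that("camera rig geometry is oblique, distinct and projective", {
  rig2 <- make_camera_rig(2)
  expect_length(rig2, 2)
  # reprojection of a known point matches a direct pinhole computation
  pc <- pinhole_camera(
    pos = c(-25, 0, 0) + 700 * c(cos(25 * pi / 180) * sin(-35 * pi / 180),
                                 -cos(25 * pi / 180) * cos(-35 * pi / 180),
                                 sin(25 * pi / 180)),
    lookat = c(-25, 0, 0))
  p <- c(12, -8, 5)
  expect_equal(as.numeric(dlt_project(rig2[[1]], p)), pc$project(p),
               tolerance = 1e-6)
  # third camera roughly perpendicular to the oblique pair
  rig3 <- make_camera_rig(3)
  dir_of <- function(cam) {
    # viewing direction from the DLT denominator row
    unname(cam$dlt[9:11] / sqrt(sum(cam$dlt[9:11]^2)))
  }
  ang12 <- acos(sum(dir_of(rig3[[1]]) * dir_of(rig3[[2]])))
  ang13 <- acos(sum(dir_of(rig3[[1]]) * dir_of(rig3[[3]])))
  expect_gt(ang12 * 180 / pi, 10)
  expect_gt(ang13 * 180 / pi, 45)
  expect_error(make_camera_rig(1), "2 or 3")
  expect_error(make_camera_rig(2, azimuths = c(10, 10)), "degenerate")
})

test_that("rendered observations are exact projections plus Gaussian noise", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  rig <- make_camera_rig(2)
  o0 <- render_observations(truth, rig, pixel_noise_sd = 0)
  proj <- dlt_project(rig[[1]], as.matrix(truth$markers$urohyal[, c("X", "Y", "Z")]))
  expect_equal(unclass(o0)[[1]][, , "urohyal"], proj, tolerance = 1e-12,
               ignore_attr = TRUE)

  # folded-normal mean of |obs - projection| with sd 0.5 px
  on <- render_observations(truth, rig, pixel_noise_sd = 0.5, seed = 9)
  dev <- abs(unclass(on)[[1]] - unclass(o0)[[1]])
  m <- mean(dev)
  expected <- 0.5 * sqrt(2 / pi)
  se <- 0.5 * sqrt(1 - 2 / pi) / sqrt(length(dev))
  expect_lt(abs(m - expected), 4 * se)

  # dropout injects roughly the requested fraction of missing values
  od <- render_observations(truth, rig, pixel_noise_sd = 0, dropout = 0.1,
                            seed = 10)
  n_slots <- truth$n_frames * length(truth$markers) * 2
  frac <- sum(is.na(unclass(od)[[1]])) / n_slots
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / (n_slots / 2)))
})

test_that("points behind a camera are flagged missing, not projected", {
  truth <- simulate_strike(strike_params(pixel_noise_sd = 0))
  rig <- make_camera_rig(2, distance = 40)  # cameras inside the scene
  obs <- render_observations(truth, rig, pixel_noise_sd = 0)
  # at this distance some caudal body markers sit behind the image plane
  expect_true(anyNA(unclass(obs)[[1]]))
})

test_that("full pipeline closure: zero noise recovers the generator exactly", {
  p <- strike_params(pixel_noise_sd = 0, skin_slip_alpha = 1)
  truth <- simulate_strike(p)
  rig <- make_camera_rig(3)
  obs <- render_observations(truth, rig, pixel_noise_sd = 0)
  rep <- process_trial(obs, rig, truth$defs, truth$roles,
                       filter_cutoff = NULL, max_gap = 0)
  expect_equal(max(rep$muscles$sh$series$strain),
               max(truth$strain$sh_internal), tolerance = 1e-6)
  expect_equal(max(rep$elevation$elevation), p$elevation_amp,
               tolerance = 1e-6)
  expect_equal(rep$muscles$sh$series$strain, truth$strain$sh_internal,
               tolerance = 1e-6)
})
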