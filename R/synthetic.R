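# Synthetic suction-strike generator: ground-truth bone poses, marker
# trajectories, muscle-length series and events, plus a multi-camera rig
# and a renderer producing noisy 2D observations. Every downstream stage
# of the pipeline can be tested against this ground truth.

#' Parameters of a synthetic suction strike
#'
#' Defaults emulate a suction-feeding strike by a ~20 cm percomorph fish
#' filmed at 500 fps: unimodal kinematic pulses peaking at peak gape, with
#' the urohyal depressing more than it retracts, the cleithrum retracting
#' more than it depresses, and urohyal excursions exceeding cleithrum
#' excursions; muscle shortening peaks ~15 ms after peak gape.
#'
#' @param frame_rate frames per second (Hz).
#' @param duration trial length (s).
#' @param t_peak_gape time of peak gape (s), strictly inside the trial.
#' @param elevation_amp peak neurocranial elevation (degrees).
#' @param urohyal_retraction_amp,urohyal_depression_amp peak urohyal marker
#'   excursions (mm).
#' @param cleithrum_retraction_amp,cleithrum_depression_amp peak cleithrum
#'   marker excursions (mm).
#' @param gape_amp peak increase of the jaw-marker distance (mm).
#' @param sh_peak_strain,epax_peak_strain peak internal muscle strain (% of
#'   initial length) for the sternohyoideus and epaxial muscles.
#' @param strain_peak_lag time from peak gape to peak muscle strain (s).
#'   With the default lag of `strain_width / 4`, peak shortening velocity
#'   falls exactly at peak gape, where peak suction power is generated.
#' @param strain_width full width (s) of the raised-cosine strain pulse.
#' @param L_i_sh,L_i_epax initial muscle lengths (mm).
#' @param skin_slip_alpha multiplicative attenuation in (0, 1] linking
#'   external (skin-marker) strain to internal strain:
#'   `s_ext = alpha * s_int`.
#' @param pixel_noise_sd SD of iid Gaussian tracking noise per image
#'   coordinate (px). The default of 0.75 px makes the synthetic
#'   neurocranium tracking precision (mean SD of pairwise marker
#'   distances) land near the ~0.17 mm typical of real marker tracking.
#' @param kin_width full width (s) of the raised-cosine kinematic pulses.
#' @param swim_speed forward whole-body drift (mm/s), removed downstream by
#'   body-plane parenting.
#' @param yaw_amp slow whole-body yaw amplitude (degrees).
#' @param seed integer seed for the rendering noise.
#' @return validated list of class `strike_params`.
#' @export
strike_params <- function(frame_rate = 500, duration = 0.2, t_peak_gape = 0.1,
                          elevation_amp = 8,
                          urohyal_retraction_amp = 2.0,
                          urohyal_depression_amp = 3.0,
                          cleithrum_retraction_amp = 1.2,
                          cleithrum_depression_amp = 0.8,
                          gape_amp = 8,
                          sh_peak_strain = 7.2, epax_peak_strain = 3.9,
                          strain_peak_lag = 0.015,
                          strain_width = 0.06,
                          L_i_sh = 10, L_i_epax = 12,
                          skin_slip_alpha = 1, pixel_noise_sd = 0.75,
                          kin_width = 0.06, swim_speed = 30, yaw_amp = 1.5,
                          seed = 1L) {
  p <- list(frame_rate = frame_rate, duration = duration,
            t_peak_gape = t_peak_gape, elevation_amp = elevation_amp,
            urohyal_retraction_amp = urohyal_retraction_amp,
            urohyal_depression_amp = urohyal_depression_amp,
            cleithrum_retraction_amp = cleithrum_retraction_amp,
            cleithrum_depression_amp = cleithrum_depression_amp,
            gape_amp = gape_amp,
            sh_peak_strain = sh_peak_strain,
            epax_peak_strain = epax_peak_strain,
            strain_peak_lag = strain_peak_lag,
            strain_width = strain_width,
            L_i_sh = L_i_sh, L_i_epax = L_i_epax,
            skin_slip_alpha = skin_slip_alpha,
            pixel_noise_sd = pixel_noise_sd, kin_width = kin_width,
            swim_speed = swim_speed, yaw_amp = yaw_amp, seed = seed)
  for (nm in names(p)) {
    if (length(p[[nm]]) != 1L || !is.finite(as.numeric(p[[nm]])))
      stop("parameter '", nm, "' must be a single finite number")
  }
  nonneg <- c("elevation_amp", "urohyal_retraction_amp",
              "urohyal_depression_amp", "cleithrum_retraction_amp",
              "cleithrum_depression_amp", "gape_amp", "sh_peak_strain",
              "epax_peak_strain", "pixel_noise_sd", "swim_speed", "yaw_amp")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0")
  for (nm in c("frame_rate", "duration", "L_i_sh", "L_i_epax",
               "strain_width", "kin_width"))
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0")
  if (p$t_peak_gape <= 0 || p$t_peak_gape >= p$duration)
    stop("parameter 't_peak_gape' must lie strictly inside (0, duration)")
  if (p$skin_slip_alpha <= 0 || p$skin_slip_alpha > 1)
    stop("parameter 'skin_slip_alpha' must be in (0, 1]")
  p$seed <- as.integer(p$seed)
  class(p) <- "strike_params"
  p
}

# Symmetric raised-cosine pulse, peak 1 at t_peak, support width w.
raised_cosine <- function(t, t_peak, w) {
  u <- (t - t_peak) / w  # in [-1/2, 1/2] inside the support
  g <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
  g
}

# Time derivative of raised_cosine.
raised_cosine_deriv <- function(t, t_peak, w) {
  u <- (t - t_peak) / w
  ifelse(abs(u) <= 0.5, -(pi / w) * sin(2 * pi * u), 0)
}

rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

unit3 <- function(v) v / sqrt(sum(v^2))

# Idealized marker layout in the body frame (mm): X rostral, Y left, Z
# dorsal, origin at the craniovertebral region. The five body-plane
# markers are laid out so that their principal axes coincide exactly with
# the body axes (centroid principal frame = body frame up to translation).
strike_layout <- function() {
  neuro <- rbind(neuro_1 = c(30, 0, 10), neuro_2 = c(22, -6, 14),
                 neuro_3 = c(22, 6, 14), neuro_4 = c(14, 0, 20))
  body <- cbind(c(0, -25, -50, -75, -100), rep(-8, 5), c(2, -3, 2, -3, 2))
  rownames(body) <- paste0("body_", 1:5)
  list(
    neuro = neuro,
    body = body,
    pivot = c(5, 0, 5),                    # craniovertebral pivot
    urohyal = c(5, -6, -15),
    cleithrum = c(-5, -7, -12),
    sh_dir = unit3(c(-1, 0, 0.2)),         # urohyal -> caudal SH end
    epax_dir = unit3(c(-1, 0, -0.1)),      # caudal neuro marker -> epaxial
    jaw_upper = c(34, 0, 0),
    jaw_lower_base = c(34, 0, -4),
    neuro_caudal = "neuro_4"
  )
}

#' Simulate a ground-truth suction strike
#'
#' Builds per-frame world poses of the neurocranium and the body plane,
#' 3D trajectories for every marker, internal and external muscle-length
#' series, kinematic truth curves and the event table. Kinematic variables
#' follow raised-cosine pulses peaking at peak gape; muscle strain follows
#' an asymmetric raised-cosine pulse peaking `strain_peak_lag` seconds
#' later. External muscle length is, by construction,
#' `L_i * (1 - alpha * s_int(t) / 100)`.
#'
#' @param params a `strike_params` object.
#' @return a list of class `strike_truth`: `params`, `time`, `n_frames`,
#'   `markers` (named list of `marker_traj3d`, world mm), `defs` (rigid
#'   body definitions for the neurocranium and body plane), `roles`
#'   (marker-role map), `body_pose` and `neuro_pose` (true world poses),
#'   `events`, `kinematics` (true curves), `strain` (internal/external
#'   strain, lengths and analytic velocities), `gape` (jaw distance).
#' @export
simulate_strike <- function(params) {
  stopifnot(inherits(params, "strike_params"))
  p <- params
  lay <- strike_layout()
  n <- floor(p$duration * p$frame_rate) + 1L
  t <- (seq_len(n) - 1) / p$frame_rate

  g_kin <- raised_cosine(t, p$t_peak_gape, p$kin_width)
  elev_deg <- p$elevation_amp * g_kin
  uro_retr <- p$urohyal_retraction_amp * g_kin
  uro_dep <- p$urohyal_depression_amp * g_kin
  cl_retr <- p$cleithrum_retraction_amp * g_kin
  cl_dep <- p$cleithrum_depression_amp * g_kin
  gape <- sqrt(sum((lay$jaw_upper - lay$jaw_lower_base)^2)) +
    p$gape_amp * g_kin

  t_strain_peak <- p$t_peak_gape + p$strain_peak_lag
  g_str <- raised_cosine(t, t_strain_peak, p$strain_width)
  dg_str <- raised_cosine_deriv(t, t_strain_peak, p$strain_width)
  s_sh_int <- p$sh_peak_strain * g_str
  s_ep_int <- p$epax_peak_strain * g_str
  a <- p$skin_slip_alpha
  L_sh_int <- p$L_i_sh * (1 - s_sh_int / 100)
  L_ep_int <- p$L_i_epax * (1 - s_ep_int / 100)
  L_sh_ext <- p$L_i_sh * (1 - a * s_sh_int / 100)
  L_ep_ext <- p$L_i_epax * (1 - a * s_ep_int / 100)

  # whole-body motion: forward drift plus a slow yaw
  yaw <- p$yaw_amp * pi / 180 * sin(pi * t / p$duration)
  markers <- c(rownames(lay$neuro), rownames(lay$body),
               "urohyal", "cleithrum", "sh_caudal", "epax",
               "jaw_upper", "jaw_lower")
  world <- array(NA_real_, c(n, 3, length(markers)),
                 dimnames = list(NULL, c("X", "Y", "Z"), markers))
  Rb_arr <- array(NA_real_, c(3, 3, n))
  tb_mat <- matrix(NA_real_, n, 3)
  Rn_arr <- array(NA_real_, c(3, 3, n))
  tn_mat <- matrix(NA_real_, n, 3)
  body_centroid <- colMeans(lay$body)

  for (f in seq_len(n)) {
    Rb <- rot_z(yaw[f])
    tb <- c(p$swim_speed * t[f], 0, 0)
    Re <- rot_y(elev_deg[f] * pi / 180)
    pb <- list()  # body-frame positions this frame
    for (m in rownames(lay$neuro))
      pb[[m]] <- lay$pivot + as.numeric(Re %*% (lay$neuro[m, ] - lay$pivot))
    for (m in rownames(lay$body)) pb[[m]] <- lay$body[m, ]
    pb$urohyal <- lay$urohyal + c(-uro_retr[f], 0, -uro_dep[f])
    pb$cleithrum <- lay$cleithrum + c(-cl_retr[f], 0, -cl_dep[f])
    pb$sh_caudal <- pb$urohyal + L_sh_ext[f] * lay$sh_dir
    pb$epax <- pb[[lay$neuro_caudal]] + L_ep_ext[f] * lay$epax_dir
    pb$jaw_upper <- lay$jaw_upper
    pb$jaw_lower <- lay$jaw_lower_base - c(0, 0, p$gape_amp * g_kin[f])
    for (m in markers)
      world[f, , m] <- as.numeric(Rb %*% pb[[m]]) + tb
    Rb_arr[, , f] <- Rb
    tb_mat[f, ] <- as.numeric(Rb %*% body_centroid) + tb
    Rn_arr[, , f] <- Rb %*% Re
    tn_mat[f, ] <- as.numeric(Rb %*% (lay$pivot - Re %*% lay$pivot)) + tb
  }

  traj <- lapply(markers, function(m)
    marker_traj3d(m, world[, , m], frame_rate = p$frame_rate))
  names(traj) <- markers

  pose <- function(id, Rarr, tmat) {
    structure(list(id = id, R = Rarr, t = tmat,
                   residual = rep(0, n), n_markers = rep(NA_integer_, n),
                   missing = rep(FALSE, n), degenerate = rep(FALSE, n),
                   frame_rate = p$frame_rate, n_frames = n),
              class = "rigid_body_pose")
  }
  pg_frame <- round(p$t_peak_gape * p$frame_rate) + 1L
  structure(list(
    params = p, time = t, n_frames = n, markers = traj,
    defs = list(
      neurocranium = rigid_body_def("neurocranium", rownames(lay$neuro),
                                    lay$neuro),
      body_plane = rigid_body_def("body_plane", rownames(lay$body),
                                  lay$body, min_markers = 5L)
    ),
    roles = list(
      neurocranium = rownames(lay$neuro),
      body_plane = rownames(lay$body),
      jaw_pair = c("jaw_upper", "jaw_lower"),
      excursion_markers = c(urohyal = "urohyal", cleithrum = "cleithrum"),
      muscles = list(sh = c("urohyal", "sh_caudal"),
                     epaxial = c(lay$neuro_caudal, "epax"))
    ),
    body_pose = pose("body_plane", Rb_arr, tb_mat),
    neuro_pose = pose("neurocranium", Rn_arr, tn_mat),
    events = data.frame(event = "peak_gape", frame = pg_frame,
                        time_s = (pg_frame - 1) / p$frame_rate),
    kinematics = data.frame(
      frame = seq_len(n), time = t, elevation = elev_deg,
      urohyal_retraction = uro_retr, urohyal_depression = uro_dep,
      cleithrum_retraction = cl_retr, cleithrum_depression = cl_dep),
    strain = data.frame(
      frame = seq_len(n), time = t,
      sh_internal = s_sh_int, sh_external = a * s_sh_int,
      epax_internal = s_ep_int, epax_external = a * s_ep_int,
      sh_length_internal = L_sh_int, sh_length_external = L_sh_ext,
      epax_length_internal = L_ep_int, epax_length_external = L_ep_ext,
      sh_velocity_internal = p$sh_peak_strain / 100 * dg_str,
      epax_velocity_internal = p$epax_peak_strain / 100 * dg_str),
    gape = gape
  ), class = "strike_truth")
}

#' @export
print.strike_truth <- function(x, ...) {
  cat("strike_truth:", x$n_frames, "frames at", x$params$frame_rate,
      "fps,", length(x$markers), "markers\n")
  invisible(x)
}

#' Build an oblique multi-camera rig
#'
#' Constructs 2 or 3 pinhole cameras (expressed as 11-parameter DLT models)
#' viewing the working volume: two oblique views, plus an optional third
#' roughly perpendicular view. Any two cameras subtend more than 10 degrees
#' at the scene centre.
#'
#' @param n_cameras 2 or 3.
#' @param lookat scene centre (mm).
#' @param distance camera distance from `lookat` (mm).
#' @param azimuths camera azimuths (degrees) in the horizontal plane; the
#'   default is `c(-35, 35)` for two cameras plus `90` for the third.
#' @param elev_deg camera elevation above the horizontal (degrees).
#' @param focal_px focal length (px).
#' @param image_size sensor size, px.
#' @return list of `camera_model`s.
#' @export
make_camera_rig <- function(n_cameras = 3, lookat = c(-25, 0, 0),
                            distance = 700, azimuths = NULL, elev_deg = 25,
                            focal_px = 3000, image_size = c(1024, 1024)) {
  if (!n_cameras %in% c(2, 3))
    stop("n_cameras must be 2 or 3")
  if (is.null(azimuths))
    azimuths <- if (n_cameras == 2) c(-35, 35) else c(-35, 35, 90)
  stopifnot(length(azimuths) == n_cameras)
  if (any(duplicated(round(azimuths, 6))))
    stop("degenerate rig: coincident camera centres")
  pairs <- utils::combn(azimuths, 2)
  if (any(abs(pairs[1, ] - pairs[2, ]) < 10))
    stop("degenerate rig: camera rays subtend < 10 degrees")
  up <- c(0, 0, 1)
  cams <- vector("list", n_cameras)
  for (i in seq_len(n_cameras)) {
    az <- azimuths[i] * pi / 180
    el <- elev_deg * pi / 180
    pos <- lookat + distance * c(cos(el) * sin(az), -cos(el) * cos(az), sin(el))
    z <- unit3(lookat - pos)
    x <- c(z[2] * up[3] - z[3] * up[2],
           z[3] * up[1] - z[1] * up[3],
           z[1] * up[2] - z[2] * up[1])
    if (sqrt(sum(x^2)) < 1e-9) stop("degenerate rig: camera looks along +Z")
    x <- unit3(x)
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    R <- rbind(x, y, z)
    tt <- -as.numeric(R %*% pos)
    K <- rbind(c(focal_px, 0, image_size[1] / 2),
               c(0, focal_px, image_size[2] / 2),
               c(0, 0, 1))
    P <- K %*% cbind(R, tt)
    P <- P / P[3, 4]
    cams[[i]] <- camera_model(c(P[1, 1:4], P[2, 1:4], P[3, 1:3]),
                              image_size = image_size,
                              id = paste0("cam", i), w_sign = 1)
  }
  names(cams) <- vapply(cams, `[[`, character(1), "id")
  cams
}

# Evaluate and restore the RNG around seeded code.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Render noisy 2D observations of a strike
#'
#' Projects every ground-truth marker through every camera and adds iid
#' Gaussian pixel noise; optionally injects random dropout (missing
#' observations). Points behind a camera are flagged missing, never
#' silently projected.
#'
#' @param truth a `strike_truth`.
#' @param rig list of `camera_model`s.
#' @param pixel_noise_sd noise SD per image coordinate (px); defaults to
#'   the generator parameter.
#' @param seed integer seed; defaults to the generator parameter.
#' @param dropout probability that a marker observation is missing in a
#'   camera-frame (default 0).
#' @return a `marker_obs2d` object (per-camera arrays frames x 2 x markers).
#' @export
render_observations <- function(truth, rig,
                                pixel_noise_sd = truth$params$pixel_noise_sd,
                                seed = truth$params$seed, dropout = 0) {
  stopifnot(inherits(truth, "strike_truth"), pixel_noise_sd >= 0,
            dropout >= 0, dropout < 1)
  markers <- names(truth$markers)
  n <- truth$n_frames
  out <- with_seed(seed, {
    arrays <- vector("list", length(rig))
    for (ci in seq_along(rig)) {
      cam <- rig[[ci]]
      arr <- array(NA_real_, c(n, 2, length(markers)),
                   dimnames = list(NULL, c("u", "v"), markers))
      for (m in markers) {
        xyz <- traj_xyz(truth$markers[[m]])
        w <- cam$w_sign * (xyz %*% cam$dlt[9:11] + 1)
        uv <- dlt_project(cam, xyz, on_infinity = "na")
        uv[w <= 0, ] <- NA_real_  # behind the camera
        if (pixel_noise_sd > 0)
          uv <- uv + matrix(stats::rnorm(length(uv), 0, pixel_noise_sd),
                            ncol = 2)
        if (dropout > 0) {
          drop <- stats::runif(n) < dropout
          uv[drop, ] <- NA_real_
        }
        arr[, , m] <- uv
      }
      arrays[[ci]] <- arr
    }
    names(arrays) <- names(rig)
    arrays
  })
  marker_obs2d(out, frame_rate = truth$params$frame_rate)
}
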