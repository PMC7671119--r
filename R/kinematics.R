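# Anatomical-coordinate-system excursions, joint-coordinate-system
# neurocranial elevation, peak-gape detection and per-trial summaries.
#
# Axis convention throughout (anatomical frame parented to the body plane):
# +X rostral, +Y left-lateral, +Z dorsal. Retraction is negative X
# translation and depression negative Z translation of a marker in this
# frame; both are reported magnitude-positive.

#' Marker excursions in the anatomical coordinate system
#'
#' Transforms a marker's world trajectory into the per-frame body-plane
#' frame (so common whole-body motion is removed), then reports retraction
#' (`-(X - mean X over the baseline window)`) and depression
#' (`-(Z - mean Z over baseline)`), in mm, shortening the spatial story to
#' "how far caudally and ventrally did this marker move relative to the
#' body".
#'
#' @param body_pose a `rigid_body_pose` for the body plane.
#' @param marker a `marker_traj3d` on the same frame grid.
#' @param baseline integer vector of pre-strike frames used to zero the
#'   series (default first 20 frames).
#' @return a data frame of class `excursion_series` with columns `frame`,
#'   `time`, `retraction`, `depression` (mm) and the ACS coordinates
#'   `acs_x`, `acs_y`, `acs_z`.
#' @export
acs_excursions <- function(body_pose, marker, baseline = 1:20) {
  n <- body_pose$n_frames
  stopifnot(nrow(marker) == n, length(baseline) >= 1)
  p <- traj_xyz(marker)
  acs <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    if (body_pose$missing[f] || anyNA(p[f, ])) next
    acs[f, ] <- crossprod(body_pose$R[, , f], p[f, ] - body_pose$t[f, ])
  }
  base <- acs[baseline, , drop = FALSE]
  if (all(!stats::complete.cases(base)))
    stop("marker '", attr(marker, "marker"),
         "' missing in the entire baseline window")
  x0 <- mean(base[, 1], na.rm = TRUE)
  z0 <- mean(base[, 3], na.rm = TRUE)
  d <- data.frame(frame = marker$frame, time = marker$time,
                  retraction = -(acs[, 1] - x0),
                  depression = -(acs[, 3] - z0),
                  acs_x = acs[, 1], acs_y = acs[, 2], acs_z = acs[, 3])
  attr(d, "marker") <- attr(marker, "marker")
  attr(d, "baseline") <- baseline
  class(d) <- c("excursion_series", "data.frame")
  d
}

# Z-Y-X (yaw-pitch-roll) Euler angles of a rotation matrix:
# R = Rz(g) %*% Ry(b) %*% Rx(a); returns c(a, b, g) in radians.
euler_zyx <- function(R) {
  b <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(b)) < 1e-9) {  # gimbal: fold roll into yaw
    a <- 0
    g <- atan2(-R[1, 2], R[2, 2])
  } else {
    a <- atan2(R[3, 2], R[3, 3])
    g <- atan2(R[2, 1], R[1, 1])
  }
  c(a, b, g)
}

#' Neurocranial elevation from a joint coordinate system
#'
#' The relative rotation of the neurocranium with respect to the body plane,
#' \eqn{R_{rel} = R_{body}^{-1} R_{neuro}}, is decomposed in Z-Y-X Euler
#' order; elevation is the rotation about the anatomical Y axis,
#' baseline-zeroed, in degrees, with dorsal rotation (nose up) positive.
#'
#' @param body_pose,neuro_pose `rigid_body_pose` series on shared frames.
#' @param baseline baseline frames for zeroing (default first 20).
#' @return a data frame of class `elevation_series` with columns `frame`,
#'   `time`, `elevation` (degrees) and `gimbal` (flag: second Euler angle
#'   within 1 degree of +/-90, where the decomposition degenerates).
#' @export
jcs_elevation <- function(body_pose, neuro_pose, baseline = 1:20) {
  n <- body_pose$n_frames
  stopifnot(neuro_pose$n_frames == n)
  ang <- rep(NA_real_, n)
  gim <- logical(n)
  for (f in seq_len(n)) {
    if (body_pose$missing[f] || neuro_pose$missing[f]) next
    Rrel <- crossprod(body_pose$R[, , f], neuro_pose$R[, , f])
    e <- euler_zyx(Rrel)
    ang[f] <- e[2] * 180 / pi
    gim[f] <- abs(abs(e[2]) - pi / 2) < pi / 180
  }
  if (all(is.na(ang[baseline])))
    stop("no valid pose in the baseline window")
  ang <- ang - mean(ang[baseline], na.rm = TRUE)
  tm <- if (!is.null(body_pose$frame_rate))
    (seq_len(n) - 1) / body_pose$frame_rate else rep(NA_real_, n)
  d <- data.frame(frame = seq_len(n), time = tm, elevation = ang, gimbal = gim)
  attr(d, "baseline") <- baseline
  class(d) <- c("elevation_series", "data.frame")
  d
}

#' Detect peak gape from a jaw-marker distance series
#'
#' Peak gape (maximum mouth opening) is the time origin for event-relative
#' reporting. It is detected as the global maximum of the jaw-marker
#' distance, optionally after a centred moving-average smooth; ties take
#' the earliest frame.
#'
#' @param gape numeric distance series (mm), `NA` allowed.
#' @param frame_rate frames per second.
#' @param smooth_window odd moving-average window in frames (1 = no
#'   smoothing).
#' @return a one-row data frame `event`, `frame`, `time_s`.
#' @export
detect_peak_gape <- function(gape, frame_rate, smooth_window = 5L) {
  if (sum(is.finite(gape)) < 3L)
    stop("gape series has fewer than 3 finite frames")
  g <- gape
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
    g <- moving_average(gape, smooth_window)
    g[!is.finite(g)] <- gape[!is.finite(g)]  # fall back near edges/gaps
  }
  f <- which(g == max(g, na.rm = TRUE))[1]
  data.frame(event = "peak_gape", frame = f, time_s = (f - 1) / frame_rate)
}

# NA-tolerant centred moving average.
moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v <- x[lo:hi]
    if (any(is.finite(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Summarize peak excursions and elevation for one trial
#'
#' @param excursions named list of `excursion_series` (e.g. `urohyal`,
#'   `cleithrum`).
#' @param elevation an `elevation_series`, or `NULL`.
#' @param events event table containing a `peak_gape` row (as produced by
#'   [detect_peak_gape()]).
#' @param frame_rate frames per second.
#' @return data frame with one row per variable: `variable`, `peak`
#'   (magnitude; mm for excursions, degrees for elevation), `peak_frame`,
#'   and `latency_ms` relative to peak gape. Ties take the earliest frame.
#' @export
summarize_trial <- function(excursions, elevation, events, frame_rate) {
  pg <- events$frame[events$event == "peak_gape"]
  if (length(pg) != 1L) stop("events must contain exactly one 'peak_gape' row")
  peak_of <- function(x) {
    if (all(!is.finite(x))) return(c(NA_real_, NA_real_))
    f <- which(x == max(x, na.rm = TRUE))[1]
    c(x[f], f)
  }
  rows <- list()
  for (nm in names(excursions)) {
    for (v in c("retraction", "depression")) {
      p <- peak_of(excursions[[nm]][[v]])
      rows[[paste(nm, v, sep = "_")]] <- p
    }
  }
  if (!is.null(elevation)) rows[["elevation"]] <- peak_of(elevation$elevation)
  out <- data.frame(
    variable = names(rows),
    peak = vapply(rows, `[`, numeric(1), 1),
    peak_frame = vapply(rows, `[`, numeric(1), 2)
  )
  out$latency_ms <- (out$peak_frame - pg) / frame_rate * 1000
  rownames(out) <- NULL
  out
}
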