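# DLT camera models, calibration from control points, and multi-view
# triangulation of tracked 2D markers.

#' Construct a DLT camera model
#'
#' An 11-parameter direct linear transformation (DLT) maps a 3D world point
#' (mm) to a 2D image point (px):
#' \deqn{u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{L_9 X + L_{10} Y + L_{11} Z + 1},\qquad
#'       v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{L_9 X + L_{10} Y + L_{11} Z + 1}.}
#'
#' @param dlt numeric vector of the 11 coefficients `L1..L11`.
#' @param image_size sensor size in px, `c(width, height)`.
#' @param id character label for the camera.
#' @param w_sign sign of the DLT denominator for points in front of the
#'   camera (+1 or -1); used for cheirality checks during rendering.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(dlt, image_size = c(1024, 1024), id = "cam", w_sign = 1) {
  dlt <- as.numeric(dlt)
  if (length(dlt) != 11L || any(!is.finite(dlt)))
    stop("'dlt' must be 11 finite coefficients")
  structure(list(dlt = dlt, image_size = as.numeric(image_size),
                 id = as.character(id), w_sign = sign(w_sign)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("DLT camera model '", x$id, "' (", x$image_size[1], "x",
      x$image_size[2], " px)\n", sep = "")
  cat("  L1..L11:", format(x$dlt, digits = 4), "\n")
  invisible(x)
}

#' Project 3D points through a DLT camera
#'
#' @param camera a `camera_model`.
#' @param points numeric N x 3 matrix (or length-3 vector) of world
#'   coordinates in mm.
#' @param on_infinity what to do when the DLT denominator is (numerically)
#'   zero: `"error"` or `"na"`.
#' @return N x 2 matrix of image coordinates (px).
#' @export
dlt_project <- function(camera, points, on_infinity = c("error", "na")) {
  on_infinity <- match.arg(on_infinity)
  stopifnot(inherits(camera, "camera_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  L <- camera$dlt
  w <- points %*% L[9:11] + 1
  bad <- abs(w) < 1e-12
  if (any(bad, na.rm = TRUE)) {
    if (on_infinity == "error")
      stop("point at infinity: DLT denominator is zero")
    w[bad] <- NA_real_
  }
  u <- (points %*% L[1:3] + L[4]) / w
  v <- (points %*% L[5:7] + L[8]) / w
  uv <- cbind(u = as.numeric(u), v = as.numeric(v))
  uv
}

#' Calibrate a DLT camera from 3D--2D control-point correspondences
#'
#' Solves the 11 DLT coefficients by linear least squares from at least six
#' non-coplanar control points, the classic videogrammetry calibration from
#' an object of known geometry (e.g. a frame carrying 26 machined circles).
#'
#' @param object_coords N x 3 matrix of control-point world coordinates (mm).
#' @param image_coords N x 2 matrix of detected image coordinates (px); rows
#'   with any `NA` are treated as unobserved in this camera.
#' @param camera_id label for the resulting camera.
#' @param image_size sensor size in px.
#' @return a list with elements `camera` (a `camera_model`), `rmse`
#'   (reprojection root-mean-square error over the used points, px) and
#'   `per_point_error` (length-N vector, px, `NA` for unused points).
#' @export
calibrate_dlt <- function(object_coords, image_coords, camera_id = "cam",
                          image_size = c(1024, 1024)) {
  object_coords <- as.matrix(object_coords)
  image_coords <- as.matrix(image_coords)
  stopifnot(ncol(object_coords) == 3, ncol(image_coords) == 2,
            nrow(object_coords) == nrow(image_coords))
  use <- stats::complete.cases(image_coords) & stats::complete.cases(object_coords)
  X <- object_coords[use, , drop = FALSE]
  UV <- image_coords[use, , drop = FALSE]
  n <- nrow(X)
  if (n < 6L)
    stop("calibration degeneracy: need >= 6 control points visible, got ", n)
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1])
    stop("calibration degeneracy: control points are coplanar")
  u <- UV[, 1]; v <- UV[, 2]
  A <- matrix(0, 2 * n, 11)
  A[seq(1, 2 * n, 2), 1:4] <- cbind(X, 1)
  A[seq(1, 2 * n, 2), 9:11] <- -u * X
  A[seq(2, 2 * n, 2), 5:8] <- cbind(X, 1)
  A[seq(2, 2 * n, 2), 9:11] <- -v * X
  b <- as.numeric(t(cbind(u, v)))
  L <- qr.coef(qr(A), b)
  w_sign <- sign(stats::median(X %*% L[9:11] + 1))
  cam <- camera_model(L, image_size = image_size, id = camera_id,
                      w_sign = if (w_sign == 0) 1 else w_sign)
  proj <- dlt_project(cam, X)
  err <- sqrt(rowSums((proj - UV)^2))
  per_point <- rep(NA_real_, nrow(object_coords))
  per_point[use] <- err
  list(camera = cam, rmse = sqrt(mean(err^2)), per_point_error = per_point)
}

#' Triangulate one 2D observation set to a 3D point
#'
#' Intersects the DLT rays of two or more cameras by homogeneous linear
#' least squares and reports the RMS reprojection residual.
#'
#' @param cameras list of `camera_model`s.
#' @param uv N_cam x 2 matrix of image observations (px), `NA` rows for
#'   cameras that do not see the point this frame.
#' @param condition_max condition number of the triangulation system above
#'   which the solution is flagged low-confidence (near-parallel rays).
#' @return a list: `xyz` (mm; `NA` if fewer than two observations),
#'   `residual` (RMS reprojection error, px), `n_cameras` used, and
#'   `low_confidence` flag.
#' @export
triangulate_point <- function(cameras, uv, condition_max = 1e6) {
  uv <- matrix(as.numeric(uv), ncol = 2)
  ok <- stats::complete.cases(uv)
  if (sum(ok) < 2L)
    return(list(xyz = rep(NA_real_, 3), residual = NA_real_,
                n_cameras = sum(ok), low_confidence = FALSE))
  A <- matrix(0, 2 * sum(ok), 3)
  b <- numeric(2 * sum(ok))
  r <- 0L
  for (i in which(ok)) {
    L <- cameras[[i]]$dlt
    u <- uv[i, 1]; v <- uv[i, 2]
    A[r + 1L, ] <- L[1:3] - u * L[9:11]
    A[r + 2L, ] <- L[5:7] - v * L[9:11]
    b[r + 1L] <- u - L[4]
    b[r + 2L] <- v - L[8]
    r <- r + 2L
  }
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[3]
  xyz <- as.numeric(sv$v %*% ((t(sv$u) %*% b) / sv$d))
  res2 <- 0
  for (i in which(ok)) {
    p <- dlt_project(cameras[[i]], xyz)
    res2 <- res2 + sum((p - uv[i, ])^2)
  }
  list(xyz = xyz, residual = sqrt(res2 / (2 * sum(ok))),
       n_cameras = sum(ok), low_confidence = is.finite(cond) && cond > condition_max)
}

#' Triangulate multi-camera 2D marker tracks into 3D trajectories
#'
#' @param cameras list of `camera_model`s (>= 2).
#' @param observations a `marker_obs2d` object (see [marker_obs2d()]) or a
#'   list of per-camera arrays of dimension frames x 2 x markers.
#' @param frame_rate frames per second, used to attach a time column.
#' @param condition_max passed to [triangulate_point()].
#' @return a named list of `marker_traj3d` data frames (one per marker) with
#'   columns `frame`, `time`, `X`, `Y`, `Z`, `residual`; frames seen by
#'   fewer than two cameras are `NA` (missing, not an error).
#' @export
triangulate <- function(cameras, observations, frame_rate = NULL,
                        condition_max = 1e6) {
  if (inherits(observations, "marker_obs2d")) {
    if (is.null(frame_rate)) frame_rate <- attr(observations, "frame_rate")
    observations <- unclass(observations)
  }
  stopifnot(length(cameras) >= 2, length(observations) == length(cameras))
  markers <- dimnames(observations[[1]])[[3]]
  n_frames <- dim(observations[[1]])[1]
  for (o in observations)
    stopifnot(dim(o)[1] == n_frames, identical(dimnames(o)[[3]], markers))
  out <- vector("list", length(markers))
  names(out) <- markers
  uv <- matrix(NA_real_, length(cameras), 2)
  for (m in seq_along(markers)) {
    xyz <- matrix(NA_real_, n_frames, 3)
    res <- rep(NA_real_, n_frames)
    lowc <- logical(n_frames)
    for (f in seq_len(n_frames)) {
      for (ci in seq_along(cameras)) uv[ci, ] <- observations[[ci]][f, , m]
      tri <- triangulate_point(cameras, uv, condition_max)
      xyz[f, ] <- tri$xyz
      res[f] <- tri$residual
      lowc[f] <- tri$low_confidence
    }
    out[[m]] <- marker_traj3d(markers[m], xyz, residual = res,
                              frame_rate = frame_rate,
                              low_confidence = lowc)
  }
  out
}

#' Construct a 3D marker trajectory
#'
#' @param marker marker id.
#' @param xyz n x 3 matrix of world coordinates (mm); `NA` rows are missing
#'   frames.
#' @param residual per-frame triangulation residual (px), optional.
#' @param frame_rate frames per second used for the `time` column
#'   (`time = (frame - 1) / frame_rate`); `NULL` leaves `time` as `NA`.
#' @param low_confidence optional logical per-frame flag.
#' @param filled optional logical per-frame flag for gap-filled frames.
#' @return a data frame of class `marker_traj3d`.
#' @export
marker_traj3d <- function(marker, xyz, residual = NULL, frame_rate = NULL,
                          low_confidence = NULL, filled = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  n <- nrow(xyz)
  miss <- !stats::complete.cases(xyz)
  xyz[miss, ] <- NA_real_
  d <- data.frame(
    frame = seq_len(n),
    time = if (is.null(frame_rate)) NA_real_ else (seq_len(n) - 1) / frame_rate,
    X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3],
    residual = if (is.null(residual)) NA_real_ else as.numeric(residual),
    low_confidence = if (is.null(low_confidence)) FALSE else low_confidence,
    filled = if (is.null(filled)) FALSE else filled
  )
  attr(d, "marker") <- as.character(marker)
  attr(d, "frame_rate") <- frame_rate
  class(d) <- c("marker_traj3d", "data.frame")
  d
}

traj_xyz <- function(traj) as.matrix(traj[, c("X", "Y", "Z")])

#' Bundle per-camera 2D observations
#'
#' @param arrays named list of per-camera arrays, each frames x 2 x markers
#'   (second dimension is `u`, `v` in px; `NA` marks a missing observation).
#' @param frame_rate frames per second.
#' @return a `marker_obs2d` object.
#' @export
marker_obs2d <- function(arrays, frame_rate) {
  stopifnot(length(arrays) >= 1, !is.null(names(arrays)))
  structure(arrays, frame_rate = frame_rate, class = "marker_obs2d")
}
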