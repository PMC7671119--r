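# File dialects: 2D points CSV, DLT coefficient CSV, 3D trajectory CSV,
# events CSV, and YAML sidecars. All output CSVs carry a leading '#' units
# comment; readers skip comment lines.

#' Write multi-camera 2D marker tracks
#'
#' One row per frame; columns `<marker>_<cam>_x`, `<marker>_<cam>_y` (px);
#' blank cells are missing observations. The frame rate goes into a YAML
#' sidecar `<file>.yaml`.
#'
#' @param obs a `marker_obs2d`.
#' @param file output CSV path.
#' @export
write_points2d_csv <- function(obs, file) {
  stopifnot(inherits(obs, "marker_obs2d"))
  cols <- list()
  for (cam in names(obs)) {
    arr <- obs[[cam]]
    for (m in dimnames(arr)[[3]]) {
      cols[[paste(m, cam, "x", sep = "_")]] <- arr[, 1, m]
      cols[[paste(m, cam, "y", sep = "_")]] <- arr[, 2, m]
    }
  }
  d <- as.data.frame(cols, check.names = FALSE)
  con <- file(file, "w")
  writeLines("# units: px; blank cell = missing observation", con)
  utils::write.csv(d, con, row.names = FALSE, na = "")
  close(con)
  yaml::write_yaml(list(frame_rate = attr(obs, "frame_rate")),
                   paste0(file, ".yaml"))
  invisible(file)
}

#' Read multi-camera 2D marker tracks
#'
#' @param file CSV path in the [write_points2d_csv()] dialect. The frame
#'   rate is read from the `<file>.yaml` sidecar unless given.
#' @param frame_rate frames per second (overrides the sidecar).
#' @return a `marker_obs2d`.
#' @export
read_points2d_csv <- function(file, frame_rate = NULL) {
  d <- utils::read.csv(file, check.names = FALSE, comment.char = "#")
  if (is.null(frame_rate)) {
    sidecar <- paste0(file, ".yaml")
    if (file.exists(sidecar))
      frame_rate <- yaml::read_yaml(sidecar)$frame_rate
  }
  m <- regmatches(names(d), regexec("^(.*)_([^_]+)_([xy])$", names(d)))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed 2D column name(s): ", paste(names(d)[bad], collapse = ", "))
  info <- data.frame(col = names(d),
                     marker = vapply(m, `[`, character(1), 2),
                     cam = vapply(m, `[`, character(1), 3),
                     axis = vapply(m, `[`, character(1), 4))
  cams <- unique(info$cam)
  markers <- unique(info$marker)
  n <- nrow(d)
  arrays <- lapply(cams, function(cam) {
    arr <- array(NA_real_, c(n, 2, length(markers)),
                 dimnames = list(NULL, c("u", "v"), markers))
    for (mk in markers) {
      cx <- info$col[info$marker == mk & info$cam == cam & info$axis == "x"]
      cy <- info$col[info$marker == mk & info$cam == cam & info$axis == "y"]
      if (length(cx) == 1) arr[, 1, mk] <- d[[cx]]
      if (length(cy) == 1) arr[, 2, mk] <- d[[cy]]
    }
    arr
  })
  names(arrays) <- cams
  marker_obs2d(arrays, frame_rate = frame_rate)
}

#' Write DLT coefficients
#'
#' The de-facto DLT coefficient layout used by XROMM-style tooling:
#' 11 rows by n-cameras columns, no header, column order = camera order.
#'
#' @param cameras list of `camera_model`s.
#' @param file output CSV path.
#' @export
write_dlt_csv <- function(cameras, file) {
  m <- vapply(cameras, `[[`, numeric(11), "dlt")
  utils::write.table(m, file, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read DLT coefficients
#'
#' @param file CSV path (11 rows x n columns, no header).
#' @param camera_ids labels, defaulting to `cam1..camN`.
#' @param image_size sensor size px.
#' @return list of `camera_model`s.
#' @export
read_dlt_csv <- function(file, camera_ids = NULL, image_size = c(1024, 1024)) {
  m <- as.matrix(utils::read.csv(file, header = FALSE))
  if (nrow(m) != 11L)
    stop("DLT file must have 11 rows, found ", nrow(m))
  if (is.null(camera_ids)) camera_ids <- paste0("cam", seq_len(ncol(m)))
  cams <- lapply(seq_len(ncol(m)), function(i)
    camera_model(m[, i], image_size = image_size, id = camera_ids[i]))
  names(cams) <- camera_ids
  cams
}

#' Write 3D marker trajectories
#'
#' Columns `<marker>_X, <marker>_Y, <marker>_Z, <marker>_res` per frame
#' (mm; residual in px).
#'
#' @param trajectories named list of `marker_traj3d`.
#' @param file output CSV path.
#' @export
write_traj3d_csv <- function(trajectories, file) {
  cols <- list()
  for (m in names(trajectories)) {
    tr <- trajectories[[m]]
    cols[[paste0(m, "_X")]] <- tr$X
    cols[[paste0(m, "_Y")]] <- tr$Y
    cols[[paste0(m, "_Z")]] <- tr$Z
    cols[[paste0(m, "_res")]] <- tr$residual
  }
  d <- as.data.frame(cols, check.names = FALSE)
  con <- file(file, "w")
  writeLines("# units: mm (X,Y,Z), px (res); blank cell = missing frame", con)
  utils::write.csv(d, con, row.names = FALSE, na = "")
  close(con)
  invisible(file)
}

#' Read 3D marker trajectories
#'
#' @param file CSV in the [write_traj3d_csv()] dialect.
#' @param frame_rate frames per second for the `time` column.
#' @return named list of `marker_traj3d`.
#' @export
read_traj3d_csv <- function(file, frame_rate = NULL) {
  d <- utils::read.csv(file, check.names = FALSE, comment.char = "#")
  m <- regmatches(names(d), regexec("^(.*)_(X|Y|Z|res)$", names(d)))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed 3D column name(s): ", paste(names(d)[bad], collapse = ", "))
  markers <- unique(vapply(m, `[`, character(1), 2))
  out <- lapply(markers, function(mk) {
    xyz <- cbind(d[[paste0(mk, "_X")]], d[[paste0(mk, "_Y")]],
                 d[[paste0(mk, "_Z")]])
    res <- d[[paste0(mk, "_res")]]
    marker_traj3d(mk, xyz, residual = res, frame_rate = frame_rate)
  })
  names(out) <- markers
  out
}

#' Write / read an events table
#'
#' Columns `event,frame,time_s`.
#' @param events data frame with columns `event`, `frame`, `time_s`.
#' @param file CSV path.
#' @export
write_events_csv <- function(events, file) {
  stopifnot(all(c("event", "frame", "time_s") %in% names(events)))
  utils::write.csv(events[, c("event", "frame", "time_s")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(file) {
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("event", "frame", "time_s") %in% names(d)))
    stop("events CSV must have columns event, frame, time_s")
  d
}

#' Write strike parameters as YAML
#'
#' @param params a `strike_params`.
#' @param file YAML path.
#' @export
write_strike_params <- function(params, file) {
  stopifnot(inherits(params, "strike_params"))
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @rdname write_strike_params
#' @export
read_strike_params <- function(file) {
  do.call(strike_params, yaml::read_yaml(file))
}

#' Write a simulated strike to disk
#'
#' Writes the per-camera 2D CSV (+ frame-rate sidecar), the ground-truth 3D
#' CSV, the DLT coefficients, the events CSV and the parameters YAML.
#'
#' @param truth a `strike_truth`.
#' @param rig list of `camera_model`s.
#' @param obs a `marker_obs2d` (e.g. from [render_observations()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_strike <- function(truth, rig, obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(points2d = file.path(dir, "points2d.csv"),
             truth3d = file.path(dir, "truth3d.csv"),
             dlt = file.path(dir, "dlt.csv"),
             events = file.path(dir, "events.csv"),
             params = file.path(dir, "params.yaml"))
  write_points2d_csv(obs, paths["points2d"])
  write_traj3d_csv(truth$markers, paths["truth3d"])
  write_dlt_csv(rig, paths["dlt"])
  write_events_csv(truth$events, paths["events"])
  write_strike_params(truth$params, paths["params"])
  invisible(paths)
}
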