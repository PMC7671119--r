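# Rigid-body pose fitting (orthogonal Procrustes), body-plane poses,
# pairwise-distance tracking precision, and gap filling.

#' Define a rigid body from reference marker coordinates
#'
#' The reference configuration is one fixed set of marker coordinates for a
#' bone or body region (in practice derived from a CT scan of the specimen,
#' or from the synthetic-strike generator).
#'
#' @param id body label.
#' @param markers character vector of marker ids (length M).
#' @param ref M x 3 matrix of reference coordinates (mm).
#' @param min_markers minimum number of markers required (3 for a bone;
#'   use 5 for the body plane, see [fit_body_plane()]).
#' @return an object of class `rigid_body_def`.
#' @export
rigid_body_def <- function(id, markers, ref, min_markers = 3L) {
  ref <- as.matrix(ref)
  stopifnot(ncol(ref) == 3, nrow(ref) == length(markers))
  if (nrow(ref) < min_markers)
    stop("rigid body '", id, "' needs >= ", min_markers, " markers")
  sv <- svd(scale(ref, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("rigid body '", id, "': reference markers are collinear")
  rownames(ref) <- markers
  structure(list(id = as.character(id), markers = as.character(markers),
                 ref = ref), class = "rigid_body_def")
}

# Kabsch / orthogonal Procrustes: least-squares R, t with det(R) = +1
# mapping ref -> obs. Returns NULL if degenerate.
kabsch <- function(ref, obs) {
  cr <- colMeans(ref); co <- colMeans(obs)
  A <- sweep(ref, 2, cr); B <- sweep(obs, 2, co)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tt <- co - as.numeric(R %*% cr)
  fit <- sweep(ref %*% t(R), 2, tt, `+`)
  list(R = R, t = tt, residual = sqrt(mean(rowSums((fit - obs)^2))))
}

#' Fit one rigid-body pose frame
#'
#' Least-squares rotation and translation (SVD-based orthogonal Procrustes
#' with a reflection guard) minimising \eqn{\sum_m \|R\,p_m + t - q_m\|^2}
#' over the markers visible this frame.
#'
#' @param def a `rigid_body_def`.
#' @param observed M x 3 matrix of observed marker coordinates (mm), rows
#'   ordered as `def$markers`; `NA` rows are treated as missing.
#' @return a list with `R` (3 x 3 proper rotation), `t` (mm), `residual`
#'   (RMS point misfit, mm), `n_markers` used, `missing` and `degenerate`
#'   flags. Fewer than three visible markers gives a missing frame;
#'   collinear visible markers give a degenerate frame.
#' @export
fit_rigid_pose <- function(def, observed) {
  observed <- as.matrix(observed)
  stopifnot(nrow(observed) == nrow(def$ref), ncol(observed) == 3)
  ok <- stats::complete.cases(observed)
  empty <- list(R = matrix(NA_real_, 3, 3), t = rep(NA_real_, 3),
                residual = NA_real_, n_markers = sum(ok),
                missing = TRUE, degenerate = FALSE)
  if (sum(ok) < 3L) return(empty)
  ref <- def$ref[ok, , drop = FALSE]
  obs <- observed[ok, , drop = FALSE]
  sv <- svd(scale(ref, center = TRUE, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    empty$degenerate <- TRUE
    return(empty)
  }
  k <- kabsch(ref, obs)
  list(R = k$R, t = k$t, residual = k$residual, n_markers = sum(ok),
       missing = FALSE, degenerate = FALSE)
}

#' Fit a rigid-body pose series from marker trajectories
#'
#' @param def a `rigid_body_def`.
#' @param trajectories named list of `marker_traj3d` containing at least the
#'   body's markers, all on the same frame grid.
#' @return an object of class `rigid_body_pose`: list with `R` (3 x 3 x n
#'   array), `t` (n x 3), `residual`, `n_markers`, `missing`, `degenerate`
#'   per frame, plus the body `id` and `frame_rate`.
#' @export
fit_rigid_body <- function(def, trajectories) {
  missing_markers <- setdiff(def$markers, names(trajectories))
  if (length(missing_markers))
    stop("trajectories missing markers: ", paste(missing_markers, collapse = ", "))
  mats <- lapply(def$markers, function(m) traj_xyz(trajectories[[m]]))
  n <- nrow(mats[[1]])
  for (m in mats) stopifnot(nrow(m) == n)
  Rarr <- array(NA_real_, c(3, 3, n))
  tmat <- matrix(NA_real_, n, 3)
  res <- rep(NA_real_, n)
  nm <- integer(n)
  miss <- logical(n); degen <- logical(n)
  obs <- matrix(NA_real_, length(mats), 3)
  for (f in seq_len(n)) {
    for (i in seq_along(mats)) obs[i, ] <- mats[[i]][f, ]
    p <- fit_rigid_pose(def, obs)
    Rarr[, , f] <- p$R
    tmat[f, ] <- p$t
    res[f] <- p$residual
    nm[f] <- p$n_markers
    miss[f] <- p$missing
    degen[f] <- p$degenerate
  }
  fr <- attr(trajectories[[def$markers[1]]], "frame_rate")
  structure(list(id = def$id, R = Rarr, t = tmat, residual = res,
                 n_markers = nm, missing = miss, degenerate = degen,
                 frame_rate = fr, n_frames = n),
            class = "rigid_body_pose")
}

#' @export
print.rigid_body_pose <- function(x, ...) {
  cat("rigid_body_pose '", x$id, "': ", x$n_frames, " frames, ",
      sum(!x$missing), " fitted, mean residual ",
      format(mean(x$residual, na.rm = TRUE), digits = 3), " mm\n", sep = "")
  invisible(x)
}

# Canonicalize a body-plane reference configuration: X along the
# rostro-caudal principal axis (sign preserving the original +X sense),
# Z the orthogonalized dorsal axis, Y completing a right-handed set,
# origin at the marker centroid.
canonical_plane_frame <- function(ref) {
  c0 <- colMeans(ref)
  Ac <- sweep(ref, 2, c0)
  sv <- svd(Ac)
  e1 <- sv$v[, 1]
  if (sum(e1 * c(1, 0, 0)) < 0) e1 <- -e1
  z <- c(0, 0, 1) - sum(c(0, 0, 1) * e1) * e1
  if (sqrt(sum(z^2)) < 1e-9) {  # plane X axis happens to be vertical
    z <- sv$v[, 3]
    if (z[3] < 0) z <- -z
  }
  z <- z / sqrt(sum(z^2))
  y <- c(z[2] * e1[3] - z[3] * e1[2],
         z[3] * e1[1] - z[1] * e1[3],
         z[1] * e1[2] - z[2] * e1[1])  # y = z x x
  Q <- cbind(e1, y, z)  # columns: new axes in old coordinates
  list(ref = Ac %*% Q, Q = Q, origin = c0)
}

#' Fit the body-plane pose series
#'
#' The body plane is a reference frame carried by at least five markers on
#' the flank of the animal; its per-frame pose is the best rigid fit to
#' those markers, and it serves as the parent frame for the anatomical
#' coordinate system. Before fitting, the reference configuration is
#' re-expressed in a canonical frame: X along the rostro-caudal principal
#' axis of the markers, Z the orthogonalized dorsal axis, Y (left-lateral)
#' completing a right-handed set, origin at the marker centroid. The
#' returned pose therefore maps that anatomical frame into world space.
#'
#' @param def a `rigid_body_def` with at least five markers.
#' @param trajectories named list of `marker_traj3d`.
#' @return a `rigid_body_pose` series (at least three markers must be
#'   visible in a frame for a pose).
#' @export
fit_body_plane <- function(def, trajectories) {
  if (length(def$markers) < 5L)
    stop("body plane requires >= 5 defined markers")
  can <- canonical_plane_frame(def$ref)
  def2 <- def
  def2$ref <- can$ref
  rownames(def2$ref) <- def$markers
  fit_rigid_body(def2, trajectories)
}

#' Tracking precision from pairwise marker distances
#'
#' Markers fixed to one rigid structure keep constant mutual distances, so
#' the standard deviation over time of each pairwise distance measures
#' tracking precision. Gap-filled frames are excluded: interpolation would
#' artificially deflate the SD.
#'
#' @param trajectories named list of `marker_traj3d`.
#' @param markers marker ids to use (>= 2).
#' @param min_frames minimum number of frames with both markers present for
#'   a pair to contribute.
#' @return a list of class `precision_report`: `pairs` data frame
#'   (`marker_a`, `marker_b`, `sd_mm`, `mean_mm`, `n_frames`), `mean_sd`
#'   (mm), `n_pairs`, and `excluded_pairs`.
#' @export
pairwise_distance_precision <- function(trajectories, markers = names(trajectories),
                                        min_frames = 2L) {
  stopifnot(length(markers) >= 2)
  pairs <- utils::combn(markers, 2)
  out <- data.frame(marker_a = pairs[1, ], marker_b = pairs[2, ],
                    sd_mm = NA_real_, mean_mm = NA_real_, n_frames = 0L)
  for (i in seq_len(ncol(pairs))) {
    ta <- trajectories[[pairs[1, i]]]
    tb <- trajectories[[pairs[2, i]]]
    keep <- !ta$filled & !tb$filled
    d <- sqrt(rowSums((traj_xyz(ta) - traj_xyz(tb))^2))
    d <- d[keep & is.finite(d)]
    out$n_frames[i] <- length(d)
    if (length(d) >= min_frames) {
      out$sd_mm[i] <- stats::sd(d)
      out$mean_mm[i] <- mean(d)
    }
  }
  valid <- !is.na(out$sd_mm)
  if (!any(valid))
    stop("no marker pair has >= ", min_frames, " joint frames")
  structure(list(pairs = out, mean_sd = mean(out$sd_mm[valid]),
                 n_pairs = ncol(pairs), excluded_pairs = sum(!valid)),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Tracking precision over", x$n_pairs, "marker pairs",
      if (x$excluded_pairs) paste0("(", x$excluded_pairs, " excluded)"), "\n")
  cat("  mean SD of pairwise distances:",
      format(x$mean_sd, digits = 3), "mm\n")
  invisible(x)
}

#' Fill short interior gaps in a 3D trajectory
#'
#' Interior runs of missing frames of length `max_gap` or shorter are
#' filled by cubic-spline interpolation per coordinate; longer runs and
#' gaps touching either end of the trial are left missing. Filled frames
#' are flagged so that precision estimates can exclude them.
#'
#' @param traj a `marker_traj3d`.
#' @param max_gap maximum gap length (frames) to fill; 0 is a no-op.
#' @return the trajectory with filled frames and updated `filled` flags.
#' @export
fill_gaps <- function(traj, max_gap) {
  stopifnot(max_gap >= 0)
  if (max_gap == 0) return(traj)
  miss <- !stats::complete.cases(traj[, c("X", "Y", "Z")])
  if (!any(miss) || all(miss)) return(traj)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill <- logical(length(miss))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    interior <- i > 1L && i < length(r$values)
    if (interior && r$lengths[i] <= max_gap)
      fill[starts[i]:ends[i]] <- TRUE
  }
  if (!any(fill)) return(traj)
  obs <- which(!miss)
  for (col in c("X", "Y", "Z")) {
    sp <- stats::spline(x = obs, y = traj[[col]][obs], xout = which(fill),
                        method = "natural")
    traj[[col]][fill] <- sp$y
  }
  traj$filled <- traj$filled | fill
  traj
}
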