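# Muscle length, strain and shortening velocity from marker pairs that
# span a muscle. Sign conventions: strain positive = shortening (% of
# initial length L_i); velocity positive = shortening (L_i per second).

#' Muscle length from a marker pair
#'
#' Euclidean 3D distance per frame between two markers placed at the ends
#' of a muscle (e.g. urohyal marker to the marker at the caudal end of the
#' sternohyoideus, or most caudal neurocranium marker to most cranial
#' epaxial marker).
#'
#' @param traj_a,traj_b `marker_traj3d` objects on the same frame grid.
#' @return numeric length series (mm); `NA` where either marker is missing.
#' @export
muscle_length <- function(traj_a, traj_b) {
  stopifnot(nrow(traj_a) == nrow(traj_b))
  len <- sqrt(rowSums((traj_xyz(traj_a) - traj_xyz(traj_b))^2))
  if (sum(is.finite(len)) < 2L)
    stop("marker pair shares fewer than 2 frames")
  len
}

#' Initial (pre-strike) muscle length
#'
#' @param length numeric length series (mm).
#' @param baseline frames of the pre-strike window (default first 20).
#' @return list with `L_i` (mean length over the finite baseline frames,
#'   mm) and `n_frames` used.
#' @export
initial_length <- function(length, baseline = 1:20) {
  stopifnot(length(baseline) >= 1)
  v <- length[baseline]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite frames in the baseline window")
  list(L_i = mean(v), n_frames = length(v))
}

#' Strain as a percentage of initial length
#'
#' \eqn{s(t) = 100\,(L_i - L(t))/L_i}; positive values indicate shortening.
#'
#' @param length numeric length series (mm).
#' @param L_i initial length (mm), > 0.
#' @return numeric strain series (% of `L_i`).
#' @export
strain_series <- function(length, L_i) {
  stopifnot(is.finite(L_i), L_i > 0)
  100 * (L_i - length) / L_i
}

# Zero-phase low-pass Butterworth filter (order 4 by default), applied
# forward and backward over a mirror-padded copy of the series so that
# start/end transients do not leak into the trial. NA-free input required.
lowpass_zero_phase <- function(x, frame_rate, cutoff, order = 4L) {
  if (cutoff >= frame_rate / 2)
    stop("filter cutoff (", cutoff, " Hz) must be below the Nyquist frequency")
  n <- length(x)
  pad <- min(n - 1L, 150L)  # long enough for band-edge transients to die
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Instantaneous shortening velocity
#'
#' The normalized length \eqn{L(t)/L_i} is optionally smoothed with a
#' zero-phase low-pass Butterworth filter, then differentiated by central
#' differences (one-sided at the ends) and negated, so that shortening is
#' positive, in units of initial lengths per second.
#'
#' @param length numeric length series (mm), gap-free over its finite span.
#' @param L_i initial length (mm).
#' @param frame_rate frames per second.
#' @param filter_cutoff low-pass cutoff in Hz, or `NULL`/`NA` to skip
#'   filtering. Must be below the Nyquist frequency.
#' @return numeric velocity series (`L_i` per second).
#' @export
velocity_series <- function(length, L_i, frame_rate, filter_cutoff = 25) {
  stopifnot(frame_rate > 0, length(length) >= 3, L_i > 0)
  nl <- length / L_i
  if (!is.null(filter_cutoff) && is.finite(filter_cutoff)) {
    ok <- is.finite(nl)
    nl[ok] <- lowpass_zero_phase(nl[ok], frame_rate, filter_cutoff)
  }
  n <- length(nl)
  v <- rep(NA_real_, n)
  v[2:(n - 1)] <- (nl[3:n] - nl[1:(n - 2)]) * frame_rate / 2
  v[1] <- (nl[2] - nl[1]) * frame_rate
  v[n] <- (nl[n] - nl[n - 1]) * frame_rate
  -v
}

#' Peak strain, peak velocity, and timing relative to peak gape
#'
#' @param strain strain series (% of `L_i`).
#' @param velocity velocity series (`L_i`/s).
#' @param frame_rate frames per second.
#' @param peak_gape_frame frame index of peak gape.
#' @return list: `peak_strain` (%), `peak_strain_latency_ms`,
#'   `peak_velocity` (`L_i`/s), `peak_velocity_latency_ms`,
#'   `velocity_at_peak_gape` (`L_i`/s; from the nearest finite frame if the
#'   event frame is missing, with `at_gape_shifted` set), and the peak
#'   frames. Ties take the earliest frame; latencies are positive after
#'   peak gape. The velocity peak is searched over interior frames only:
#'   the one-sided endpoint differences carry twice the noise variance and
#'   would otherwise dominate spuriously.
#' @export
peak_strain_and_velocity <- function(strain, velocity, frame_rate,
                                     peak_gape_frame) {
  n <- length(strain)
  stopifnot(length(velocity) == n,
            peak_gape_frame >= 1, peak_gape_frame <= n)
  pk <- function(x) which(x == max(x, na.rm = TRUE))[1]
  fs <- pk(strain)
  v_int <- velocity
  if (n > 4L) v_int[c(1L, n)] <- NA
  fv <- pk(v_int)
  shifted <- FALSE
  fg <- peak_gape_frame
  if (!is.finite(velocity[fg])) {
    fin <- which(is.finite(velocity))
    fg <- fin[which.min(abs(fin - peak_gape_frame))]
    shifted <- TRUE
  }
  lat <- function(f) (f - peak_gape_frame) / frame_rate * 1000
  list(peak_strain = strain[fs], peak_strain_frame = fs,
       peak_strain_latency_ms = lat(fs),
       peak_velocity = velocity[fv], peak_velocity_frame = fv,
       peak_velocity_latency_ms = lat(fv),
       velocity_at_peak_gape = velocity[fg],
       at_gape_shifted = shifted)
}

#' Full strain analysis for one muscle
#'
#' Convenience wrapper: length from the marker pair, initial length from
#' the baseline window, strain on the (optionally zero-phase low-pass
#' filtered) normalized length, velocity, and event-relative peaks.
#'
#' @param traj_a,traj_b `marker_traj3d` marker pair spanning the muscle.
#' @param frame_rate frames per second.
#' @param baseline pre-strike frames for `L_i` (default first 20).
#' @param filter_cutoff Hz, or `NULL` for no filtering. The same filtered
#'   normalized-length series feeds both strain and velocity, so their
#'   peaks share a common smoothing.
#' @param peak_gape_frame frame of peak gape (for latencies), or `NULL`.
#' @param muscle label.
#' @return list of class `strain_analysis`: `series` data frame (`frame`,
#'   `time`, `length`, `norm_length`, `strain`, `velocity`), `L_i`,
#'   `muscle`, `filter_cutoff`, and `peaks` (when `peak_gape_frame` given).
#' @export
analyze_muscle <- function(traj_a, traj_b, frame_rate, baseline = 1:20,
                           filter_cutoff = 25, peak_gape_frame = NULL,
                           muscle = "muscle") {
  len <- muscle_length(traj_a, traj_b)
  L_i <- initial_length(len, baseline)$L_i
  nl <- len / L_i
  if (!is.null(filter_cutoff) && is.finite(filter_cutoff)) {
    ok <- is.finite(nl)
    nl[ok] <- lowpass_zero_phase(nl[ok], frame_rate, filter_cutoff)
  }
  strain <- 100 * (1 - nl)
  vel <- velocity_series(nl * L_i, L_i, frame_rate, filter_cutoff = NULL)
  d <- data.frame(frame = seq_along(len), time = (seq_along(len) - 1) / frame_rate,
                  length = len, norm_length = nl, strain = strain,
                  velocity = vel)
  out <- list(series = d, L_i = L_i, muscle = muscle,
              filter_cutoff = filter_cutoff)
  if (!is.null(peak_gape_frame))
    out$peaks <- peak_strain_and_velocity(strain, vel, frame_rate,
                                          peak_gape_frame)
  class(out) <- "strain_analysis"
  out
}

#' @export
print.strain_analysis <- function(x, ...) {
  cat("strain_analysis '", x$muscle, "': L_i = ",
      format(x$L_i, digits = 4), " mm\n", sep = "")
  if (!is.null(x$peaks))
    cat("  peak strain ", format(x$peaks$peak_strain, digits = 3), "% at ",
        format(x$peaks$peak_strain_latency_ms, digits = 3),
        " ms after peak gape; peak velocity ",
        format(x$peaks$peak_velocity, digits = 3), " L_i/s\n", sep = "")
  invisible(x)
}
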