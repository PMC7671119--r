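# End-to-end orchestration: triangulate -> poses -> kinematics -> strain
# -> summaries, from in-memory objects or from a YAML trial config; plus
# the simulated external-vs-internal validation experiment.

#' Write / read a rigid-body definition CSV
#'
#' Columns `marker,X,Y,Z` (reference coordinates, mm).
#' @param def a `rigid_body_def`.
#' @param file CSV path.
#' @export
write_body_def_csv <- function(def, file) {
  d <- data.frame(marker = def$markers, X = def$ref[, 1],
                  Y = def$ref[, 2], Z = def$ref[, 3])
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_body_def_csv
#' @param id body label.
#' @param min_markers minimum marker count (5 for the body plane).
#' @export
read_body_def_csv <- function(file, id, min_markers = 3L) {
  d <- utils::read.csv(file, comment.char = "#")
  if (!all(c("marker", "X", "Y", "Z") %in% names(d)))
    stop("body definition CSV must have columns marker, X, Y, Z")
  rigid_body_def(id, d$marker, as.matrix(d[, c("X", "Y", "Z")]),
                 min_markers = min_markers)
}

#' Process one trial from observations to summaries
#'
#' The core pipeline: triangulate 2D tracks (or accept 3D trajectories
#' directly), fill short gaps, fit the neurocranium and body-plane poses,
#' detect peak gape (unless supplied), compute anatomical-frame excursions
#' and neurocranial elevation, muscle strain and shortening velocity, and
#' the tracking-precision report.
#'
#' @param observations a `marker_obs2d`, or a named list of `marker_traj3d`
#'   (already-triangulated input).
#' @param cameras list of `camera_model`s (required when `observations` is
#'   2D).
#' @param defs list with `rigid_body_def`s `neurocranium` and `body_plane`.
#' @param roles marker-role map: `jaw_pair` (length-2 character, optional
#'   when `events` is supplied), `excursion_markers` (named character),
#'   `muscles` (named list of length-2 character marker pairs).
#' @param frame_rate frames per second (defaults to the observations').
#' @param baseline pre-strike frames used for all baselines (excursions,
#'   elevation and initial muscle length share the same window).
#' @param filter_cutoff zero-phase low-pass cutoff (Hz) for strain and
#'   velocity; `NULL` disables filtering.
#' @param max_gap maximum interior gap (frames) to fill by cubic
#'   interpolation before pose fitting.
#' @param events optional events table with a `peak_gape` row; if absent,
#'   peak gape is detected from the jaw pair.
#' @return list of class `trial_report`: `trajectories`, `poses`,
#'   `events`, `excursions`, `elevation`, `muscles` (list of
#'   `strain_analysis`), `precision` (neurocranium `precision_report`),
#'   `summary` (peaks table including muscle peaks), and `qc` (counts of
#'   flagged frames).
#' @export
process_trial <- function(observations, cameras = NULL, defs, roles,
                          frame_rate = NULL, baseline = 1:20,
                          filter_cutoff = 25, max_gap = 5, events = NULL) {
  if (inherits(observations, "marker_obs2d")) {
    if (is.null(cameras))
      stop("2D observations require 'cameras'")
    if (is.null(frame_rate)) frame_rate <- attr(observations, "frame_rate")
    traj <- triangulate(cameras, observations, frame_rate = frame_rate)
  } else {
    traj <- observations
    if (is.null(frame_rate))
      frame_rate <- attr(traj[[1]], "frame_rate")
  }
  if (is.null(frame_rate) || !is.finite(frame_rate) || frame_rate <= 0)
    stop("a positive frame_rate is required")

  needed <- unique(c(defs$neurocranium$markers, defs$body_plane$markers,
                     roles$jaw_pair, unname(roles$excursion_markers),
                     unlist(roles$muscles)))
  absent <- setdiff(needed, names(traj))
  if (length(absent))
    stop("mapped marker(s) absent from the data: ",
         paste(absent, collapse = ", "))

  raw_traj <- traj
  if (max_gap > 0) traj <- lapply(traj, fill_gaps, max_gap = max_gap)

  neuro_pose <- fit_rigid_body(defs$neurocranium, traj)
  body_pose <- fit_body_plane(defs$body_plane, traj)

  if (is.null(events)) {
    if (length(roles$jaw_pair) != 2L)
      stop("no events supplied and no jaw pair mapped: cannot locate peak gape")
    gape <- muscle_length(traj[[roles$jaw_pair[1]]], traj[[roles$jaw_pair[2]]])
    events <- detect_peak_gape(gape, frame_rate)
  }
  pg <- events$frame[events$event == "peak_gape"]
  if (length(pg) != 1L)
    stop("events must contain exactly one 'peak_gape' row")

  excursions <- lapply(roles$excursion_markers, function(m)
    acs_excursions(body_pose, traj[[m]], baseline))
  elevation <- jcs_elevation(body_pose, neuro_pose, baseline)

  muscles <- list()
  for (nm in names(roles$muscles)) {
    pr <- roles$muscles[[nm]]
    muscles[[nm]] <- analyze_muscle(traj[[pr[1]]], traj[[pr[2]]], frame_rate,
                                    baseline = baseline,
                                    filter_cutoff = filter_cutoff,
                                    peak_gape_frame = pg, muscle = nm)
  }

  precision <- pairwise_distance_precision(
    raw_traj[defs$neurocranium$markers])

  summary <- summarize_trial(excursions, elevation, events, frame_rate)
  for (nm in names(muscles)) {
    pk <- muscles[[nm]]$peaks
    summary <- rbind(summary, data.frame(
      variable = paste0(nm, c("_peak_strain", "_peak_velocity")),
      peak = c(pk$peak_strain, pk$peak_velocity),
      peak_frame = c(pk$peak_strain_frame, pk$peak_velocity_frame),
      latency_ms = c(pk$peak_strain_latency_ms, pk$peak_velocity_latency_ms)))
    summary <- rbind(summary, data.frame(
      variable = paste0(nm, "_velocity_at_peak_gape"),
      peak = pk$velocity_at_peak_gape, peak_frame = pg, latency_ms = 0))
  }

  qc <- list(
    n_frames = body_pose$n_frames,
    filled_frames = sum(vapply(traj, function(x) sum(x$filled), numeric(1))),
    low_confidence_frames = sum(vapply(traj, function(x)
      sum(x$low_confidence, na.rm = TRUE), numeric(1))),
    missing_pose_frames = sum(body_pose$missing) + sum(neuro_pose$missing),
    gimbal_frames = sum(elevation$gimbal, na.rm = TRUE)
  )
  qc$clean <- qc$filled_frames + qc$low_confidence_frames +
    qc$missing_pose_frames + qc$gimbal_frames == 0

  structure(list(trajectories = traj,
                 poses = list(neurocranium = neuro_pose, body_plane = body_pose),
                 events = events, excursions = excursions,
                 elevation = elevation, muscles = muscles,
                 precision = precision, summary = summary,
                 frame_rate = frame_rate, qc = qc),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("trial_report:", x$qc$n_frames, "frames; peak gape at frame",
      x$events$frame[x$events$event == "peak_gape"], "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Run one trial from a YAML configuration
#'
#' Config keys: `points2d` (2D CSV path), `dlt` (DLT CSV) *or*
#' `trajectories` (3D CSV), `bodies` (named paths to body-definition CSVs;
#' must include `neurocranium` and exactly one `body_plane`), `roles`
#' (`jaw_pair`, `excursion_markers`, `muscles`), optional `events` CSV,
#' `frame_rate`, `baseline` (`[first, last]`), `filter_cutoff`, `max_gap`,
#' `out_dir`, `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return the `trial_report`, invisibly; outputs are written under
#'   `out_dir` when set (3D trajectories, excursion/elevation/strain CSVs,
#'   `summary.json` including a QC section and provenance log).
#' @export
run_trial <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  need <- function(key) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
    config[[key]]
  }
  if (is.null(config$bodies$body_plane) ||
      length(config$bodies) < 2L)
    stop("config must define bodies: neurocranium and exactly one body_plane")
  defs <- list(
    neurocranium = read_body_def_csv(need("bodies")$neurocranium,
                                     "neurocranium"),
    body_plane = read_body_def_csv(config$bodies$body_plane, "body_plane",
                                   min_markers = 5L)
  )
  roles <- need("roles")
  roles$excursion_markers <- unlist(roles$excursion_markers)
  frame_rate <- config$frame_rate
  if (!is.null(config$points2d)) {
    observations <- read_points2d_csv(config$points2d, frame_rate)
    cameras <- read_dlt_csv(need("dlt"))
  } else {
    observations <- read_traj3d_csv(need("trajectories"), frame_rate)
    cameras <- NULL
  }
  events <- if (!is.null(config$events)) read_events_csv(config$events)
  baseline <- if (!is.null(config$baseline))
    seq(config$baseline[1], config$baseline[2]) else 1:20
  rep <- process_trial(observations, cameras, defs, roles,
                       frame_rate = frame_rate, baseline = baseline,
                       filter_cutoff = {
                         fc <- config$filter_cutoff
                         if (is.null(fc)) fc <- 25
                         if (fc <= 0) NULL else fc  # 0 switches filtering off
                       },
                       max_gap = if (is.null(config$max_gap)) 5
                         else config$max_gap,
                       events = events)
  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_traj3d_csv(rep$trajectories, file.path(out, "trajectories3d.csv"))
    write_events_csv(rep$events, file.path(out, "events.csv"))
    exc <- data.frame(frame = rep$elevation$frame,
                      time_s = rep$elevation$time)
    for (nm in names(rep$excursions)) {
      exc[[paste0(nm, "_retraction_mm")]] <- rep$excursions[[nm]]$retraction
      exc[[paste0(nm, "_depression_mm")]] <- rep$excursions[[nm]]$depression
    }
    exc$elevation_deg <- rep$elevation$elevation
    con <- file(file.path(out, "kinematics.csv"), "w")
    writeLines("# units: mm (excursions), degrees (elevation), s (time)", con)
    utils::write.csv(exc, con, row.names = FALSE, na = "")
    close(con)
    for (nm in names(rep$muscles)) {
      con <- file(file.path(out, paste0("strain_", nm, ".csv")), "w")
      writeLines("# units: mm (length), % of L_i (strain), L_i/s (velocity)",
                 con)
      utils::write.csv(rep$muscles[[nm]]$series, con, row.names = FALSE,
                       na = "")
      close(con)
    }
    log <- list(
      package_version = as.character(utils::packageVersion("vromm")),
      config_md5 = if (!is.null(cfg_path))
        unname(tools::md5sum(cfg_path)) else NA,
      seed = config$seed
    )
    jsonlite::write_json(
      list(summary = rep$summary,
           precision_mean_sd_mm = rep$precision$mean_sd,
           qc = rep$qc, log = log),
      file.path(out, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(rep)
}

#' Simulated external-vs-internal strain validation experiment
#'
#' Mirrors the design of validating skin-marker strain against an implanted
#' -marker reference: paired external and internal strain series for
#' `n_strikes` feeding strikes of one individual. External strain is the
#' skin-slip-attenuated internal strain plus Gaussian measurement noise on
#' the strain scale. Each strike is regressed externally-on-internally and
#' the per-trial slopes and RMSEs pooled.
#'
#' @param pairs optional list of data frames with columns `external` and
#'   `internal` (% strain); when supplied, no simulation is run.
#' @param n_strikes number of simulated strikes.
#' @param skin_slip_alpha multiplicative strain attenuation in (0, 1].
#' @param strain_noise_sd SD of additive strain noise (% strain).
#' @param params `strike_params` for the simulated strikes.
#' @param seed integer seed.
#' @return a `validation_report` (see [pool_validation()]).
#' @export
run_validation_experiment <- function(pairs = NULL, n_strikes = 7,
                                      skin_slip_alpha = 0.90,
                                      strain_noise_sd = 0.5,
                                      params = NULL, seed = 1L) {
  if (is.null(pairs)) {
    stopifnot(n_strikes >= 1)
    if (is.null(params))
      params <- strike_params(skin_slip_alpha = skin_slip_alpha, seed = seed)
    else {
      params$skin_slip_alpha <- skin_slip_alpha
      params <- do.call(strike_params, unclass(params))
    }
    pairs <- with_seed(seed, lapply(seq_len(n_strikes), function(i) {
      truth <- simulate_strike(params)
      ext <- truth$strain$sh_external
      if (strain_noise_sd > 0)
        ext <- ext + stats::rnorm(length(ext), 0, strain_noise_sd)
      data.frame(external = ext, internal = truth$strain$sh_internal)
    }))
  }
  if (length(pairs) < 1L) stop("need at least one paired trial")
  comparisons <- lapply(pairs, function(p) {
    if (!all(c("external", "internal") %in% names(p)))
      stop("each pair needs 'external' and 'internal' columns")
    compare_strain_methods(p$external, p$internal)
  })
  pool_validation(comparisons)
}
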