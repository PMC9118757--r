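#' Phase-segmentation parameters
#'
#' @param confinement_threshold Frames whose windowed confinement ratio
#'   exceeds this value are "go" (directed), the rest "stop". Study value
#'   0.8.
#' @param window_frames Odd sliding-window length (frames) for the
#'   confinement ratio. A pause is only detectable when it fills roughly
#'   half a window, so the window caps the temporal resolution: at 20 Hz
#'   the default of 5 frames (0.25 s) resolves pauses down to about 0.15 s.
#'   See the package vignette for the resolution analysis.
#' @param min_phase_frames Minimum phase duration; shorter runs are merged
#'   into their neighbours (suppresses single-frame threshold chatter).
#' @param min_directed_displacement_um Net displacement at least one go
#'   phase must reach for the trajectory to count as directed ("moving").
#' @return Object of class `phase_params`.
#' @export
phase_params <- function(confinement_threshold = 0.8, window_frames = 5,
                         min_phase_frames = 2,
                         min_directed_displacement_um = 1.0) {
  assert_number(confinement_threshold, "confinement_threshold", 0, strict = TRUE)
  if (confinement_threshold > 1) {
    stop("validation error: `confinement_threshold` must lie in (0, 1]",
         call. = FALSE)
  }
  assert_number(window_frames, "window_frames", 3)
  if (window_frames %% 2 != 1) {
    stop("validation error: `window_frames` must be odd", call. = FALSE)
  }
  assert_number(min_phase_frames, "min_phase_frames", 1)
  assert_number(min_directed_displacement_um, "min_directed_displacement_um", 0)
  structure(list(confinement_threshold = confinement_threshold,
                 window_frames = as.integer(window_frames),
                 min_phase_frames = as.integer(min_phase_frames),
                 min_directed_displacement_um = min_directed_displacement_um),
            class = "phase_params")
}

#' Sliding-window confinement ratio
#'
#' For each spot of a trajectory, the ratio of the net displacement between
#' the endpoints of a centered window to the summed step path length inside
#' it: near 1 for directed motion, near 0 for confined or stationary
#' motion. Windows are truncated at the trajectory ends; trajectories
#' shorter than the window use the whole trajectory for every frame.
#' Zero-path windows yield 0.
#'
#' @param trajectory Single-particle data frame with `x_px`, `y_px` ordered
#'   by `frame`.
#' @param params A [phase_params()].
#' @return Numeric vector in `[0, 1]`, one value per spot.
#' @export
confinement_ratio_profile <- function(trajectory, params = phase_params()) {
  n <- nrow(trajectory)
  if (n < 2) return(rep(0, n))
  x <- trajectory$x_px
  y <- trajectory$y_px
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  cpath <- c(0, cumsum(steps))
  half <- (min(params$window_frames, n) - 1) %/% 2
  if (n < params$window_frames) {
    a <- rep(1L, n)
    b <- rep(n, n)
  } else {
    a <- pmax(seq_len(n) - half, 1L)
    b <- pmin(seq_len(n) + half, n)
  }
  net <- sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2)
  path <- cpath[b] - cpath[a]
  ratio <- ifelse(path > 0, net / path, 0)
  pmin(pmax(ratio, 0), 1)
}

# Iteratively absorb runs shorter than min_len by flipping their label
# (shortest first; earliest on ties), until all phases are long enough or
# a single phase remains.
merge_short_runs <- function(labels, min_len) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    labels[starts[j]:ends[j]] <- !r$values[j]
  }
  labels
}

#' Parse a trajectory into go and stop phases
#'
#' Thresholds the windowed confinement ratio (go where ratio >
#' `confinement_threshold`), absorbs runs shorter than `min_phase_frames`
#' into their neighbours, and returns the maximal phases, which partition
#' the trajectory's spots.
#'
#' Step attribution: the step from spot `k` to `k + 1` belongs to the phase
#' of spot `k` (the phase label describes the motion state over the
#' following inter-frame interval), so a phase of `m` spots spans `m` frame
#' intervals of motion except for the trajectory's final phase.
#'
#' @param trajectory Single-particle data frame ordered by `frame`.
#' @param params A [phase_params()].
#' @param geometry An [acquisition_geometry()] for physical units.
#' @return Data frame of phases: `kind` ("go"/"stop"), `start_idx`,
#'   `end_idx` (1-based spot indices), `start_frame`, `end_frame`,
#'   `n_frames`, `duration_s`, `path_length_um`, `net_displacement_um`.
#' @export
parse_phases <- function(trajectory, params = phase_params(),
                         geometry = acquisition_geometry()) {
  n <- nrow(trajectory)
  if (n < 2) {
    stop("validation error: motion analysis needs >= 2 spots", call. = FALSE)
  }
  if (is.unsorted(trajectory$frame, strictly = TRUE)) {
    stop("validation error: frames must be strictly increasing", call. = FALSE)
  }
  ratio <- confinement_ratio_profile(trajectory, params)
  go <- ratio > params$confinement_threshold
  go <- merge_short_runs(go, params$min_phase_frames)

  r <- rle(go)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  x_um <- px_to_um(trajectory$x_px, geometry)
  y_um <- px_to_um(trajectory$y_px, geometry)
  steps <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  cpath <- c(0, cumsum(steps))

  # step k (spot k -> k+1) belongs to the phase of spot k: the label is the
  # motion state over the following inter-frame interval. The trajectory's
  # final phase therefore spans one interval less than its spot count, and
  # the phase durations sum to the observation span (n - 1 intervals).
  path <- cpath[pmin(ends + 1, n)] - cpath[starts]
  net_end <- pmin(ends + 1, n)
  net <- sqrt((x_um[net_end] - x_um[starts])^2 +
                (y_um[net_end] - y_um[starts])^2)
  intervals <- r$lengths
  intervals[length(intervals)] <- intervals[length(intervals)] - 1L
  data.frame(
    kind = ifelse(r$values, "go", "stop"),
    start_idx = starts, end_idx = ends,
    start_frame = trajectory$frame[starts],
    end_frame = trajectory$frame[ends],
    n_frames = r$lengths,
    duration_s = intervals / geometry$frame_rate_hz,
    path_length_um = path,
    net_displacement_um = pmin(net, path),
    stringsAsFactors = FALSE)
}

#' Per-trajectory transport parameters
#'
#' The four study readouts plus the total run length:
#' \itemize{
#'   \item velocity: total go path length / total go time (time-weighted
#'     mean speed over go phases);
#'   \item run length: mean go-phase path length (the mean go-phase net
#'     displacement is also reported);
#'   \item pausing time: mean stop-phase duration;
#'   \item pausing frequency: stop events per minute of observed trajectory
#'     duration;
#'   \item total length: sum of go-phase run lengths.
#' }
#'
#' @param trajectory Single-particle data frame ordered by `frame`.
#' @param phases Output of [parse_phases()] for the same trajectory.
#' @param geometry An [acquisition_geometry()].
#' @return One-row data frame: `velocity_um_s`, `run_length_um`,
#'   `run_net_um`, `pausing_time_s`, `pausing_frequency_per_min`,
#'   `total_length_um`, `n_go`, `n_stop`, `duration_s`. Velocity and run
#'   length are `NA` (undefined) when there is no go phase.
#' @export
transport_parameters <- function(trajectory, phases,
                                 geometry = acquisition_geometry()) {
  go <- phases[phases$kind == "go", , drop = FALSE]
  stop_ <- phases[phases$kind == "stop", , drop = FALSE]
  duration_s <- (nrow(trajectory) - 1) / geometry$frame_rate_hz
  n_go <- nrow(go)
  n_stop <- nrow(stop_)
  data.frame(
    velocity_um_s = if (n_go > 0) sum(go$path_length_um) / sum(go$duration_s)
      else NA_real_,
    run_length_um = if (n_go > 0) mean(go$path_length_um) else NA_real_,
    run_net_um = if (n_go > 0) mean(go$net_displacement_um) else NA_real_,
    pausing_time_s = if (n_stop > 0) mean(stop_$duration_s) else NA_real_,
    pausing_frequency_per_min = n_stop / (duration_s / 60),
    total_length_um = if (n_go > 0) sum(go$path_length_um) else 0,
    n_go = n_go, n_stop = n_stop, duration_s = duration_s)
}

#' Classify a trajectory as directed ("moving")
#'
#' `TRUE` when at least one go phase achieves a net displacement of
#' `min_directed_displacement_um`.
#'
#' @param trajectory Single-particle data frame (unused beyond validation;
#'   kept for a uniform signature).
#' @param phases Output of [parse_phases()].
#' @param params A [phase_params()].
#' @return Logical scalar.
#' @export
classify_moving <- function(trajectory, phases, params = phase_params()) {
  go <- phases[phases$kind == "go", , drop = FALSE]
  nrow(go) > 0 &&
    any(go$net_displacement_um >= params$min_directed_displacement_um)
}

#' Analyze every trajectory of a table
#'
#' Runs [parse_phases()], [transport_parameters()] and [classify_moving()]
#' on each particle.
#'
#' @param trajectories Trajectory table.
#' @param geometry An [acquisition_geometry()].
#' @param params A [phase_params()].
#' @return Data frame with one row per trajectory: annotations, transport
#'   parameters, `moving`, `n_spots` and `median_sigma_px`.
#' @export
analyze_trajectories <- function(trajectories,
                                 geometry = acquisition_geometry(),
                                 params = phase_params()) {
  parts <- split_trajectories(trajectories)
  rows <- lapply(parts, function(p) {
    if (nrow(p) < 2) return(NULL)
    ph <- parse_phases(p, params, geometry)
    tp <- transport_parameters(p, ph, geometry)
    ann <- data.frame(
      fov_id = p$fov_id[1] %||% "fov1",
      condition = p$condition[1] %||% "none",
      channel = p$channel[1] %||% "red",
      particle_id = p$particle_id[1],
      n_spots = nrow(p),
      median_sigma_px = median(p$sigma_px),
      moving = classify_moving(p, ph, params),
      stringsAsFactors = FALSE)
    cbind(ann, tp)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(fov_id = character(), condition = character(),
                      channel = character(), particle_id = integer(),
                      n_spots = integer(), median_sigma_px = numeric(),
                      moving = logical(), velocity_um_s = numeric(),
                      run_length_um = numeric(), run_net_um = numeric(),
                      pausing_time_s = numeric(),
                      pausing_frequency_per_min = numeric(),
                      total_length_um = numeric(), n_go = integer(),
                      n_stop = integer(), duration_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$channel, out$particle_id), , drop = FALSE]
}

#' Per-field-of-view summary
#'
#' Counts detected and directed trajectories per field of view and returns
#' the per-trajectory parameter table restricted to the moving trajectories
#' (the unit plotted in per-trajectory comparisons).
#'
#' @param trajectories Trajectory table (possibly several `fov_id`s).
#' @param geometry An [acquisition_geometry()].
#' @param params A [phase_params()].
#' @return List with `summary` (per FoV: `n_particles`, `n_moving`,
#'   `moving_fraction`), `parameters` (per-trajectory table, movers only)
#'   and `trajectories` (full per-trajectory table).
#' @export
summarize_fov <- function(trajectories, geometry = acquisition_geometry(),
                          params = phase_params()) {
  tab <- analyze_trajectories(trajectories, geometry, params)
  if (nrow(tab) == 0) {
    summary <- data.frame(fov_id = character(), condition = character(),
                          n_particles = integer(), n_moving = integer(),
                          moving_fraction = numeric(),
                          stringsAsFactors = FALSE)
    if (nrow(trajectories) == 0) {
      summary <- data.frame(fov_id = "fov1", condition = "none",
                            n_particles = 0L, n_moving = 0L,
                            moving_fraction = NA_real_,
                            stringsAsFactors = FALSE)
    }
    return(list(summary = summary, parameters = tab, trajectories = tab))
  }
  key <- interaction(tab$fov_id, tab$condition, drop = TRUE)
  groups <- split(tab, key)
  summary <- do.call(rbind, lapply(groups, function(g) {
    data.frame(fov_id = g$fov_id[1], condition = g$condition[1],
               n_particles = nrow(g), n_moving = sum(g$moving),
               moving_fraction = sum(g$moving) / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(summary = summary,
       parameters = tab[tab$moving, , drop = FALSE],
       trajectories = tab)
}
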