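#' Intermittent-motion model
#'
#' Two-state (go/stop) motion of organelle cargoes along branch-like paths.
#' A moving particle alternates exponentially distributed go phases, during
#' which it advances along its branch at `v_go_um_s`, and stop phases during
#' which it only jitters. Phase switching is memoryless; `p_stop` is the
#' probability that a go phase is followed by a pause (with `p_stop = 0` the
#' particle never pauses). A `1 - p_moving` share of particles is fully
#' static.
#'
#' @param v_go_um_s Speed during go phases (um/s).
#' @param go_duration_s,stop_duration_s Mean phase durations (s, exponential).
#' @param jitter_sd_nm Isotropic per-frame positional jitter (nm), applied in
#'   both phases; localization-scale (defaults to 10 nm).
#' @param branch Optional polyline (matrix with columns x, y in um) that all
#'   particles follow. `NULL` assigns each particle its own straight
#'   horizontal lane spanning the field of view.
#' @param p_moving Fraction of particles that ever move.
#' @param p_stop Probability that a go phase is followed by a stop phase.
#' @return Object of class `motion_model`.
#' @export
motion_model <- function(v_go_um_s = 1.0, go_duration_s = 2.0,
                         stop_duration_s = 1.0, jitter_sd_nm = 10,
                         branch = NULL, p_moving = 0.3, p_stop = 1.0) {
  assert_number(v_go_um_s, "v_go_um_s", 0)
  assert_number(go_duration_s, "go_duration_s", 0, strict = TRUE)
  assert_number(stop_duration_s, "stop_duration_s", 0, strict = TRUE)
  assert_number(jitter_sd_nm, "jitter_sd_nm", 0)
  assert_number(p_moving, "p_moving", 0)
  assert_number(p_stop, "p_stop", 0)
  if (p_moving > 1 || p_stop > 1) {
    stop("validation error: p_moving and p_stop must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(branch)) {
    branch <- as.matrix(branch)
    if (ncol(branch) != 2 || nrow(branch) < 2) {
      stop("validation error: `branch` must be a polyline matrix (x, y) um",
           call. = FALSE)
    }
  }
  structure(list(v_go_um_s = v_go_um_s, go_duration_s = go_duration_s,
                 stop_duration_s = stop_duration_s,
                 jitter_sd_nm = jitter_sd_nm, branch = branch,
                 p_moving = p_moving, p_stop = p_stop),
            class = "motion_model")
}

#' Optics and noise model
#'
#' Emitters are rendered as pixel-integrated 2-D Gaussians of SD
#' `sqrt(sigma_psf_nm^2 + object_sigma_nm^2)` (PSF convolved with a Gaussian
#' object); pixel values are `Poisson(signal + background)` plus Gaussian
#' read noise.
#'
#' @param sigma_psf_nm PSF Gaussian SD (nm); 112 nm measured default.
#' @param photons_per_frame Expected total counts per emitter per frame.
#' @param background_counts Mean background per pixel.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param object_sigma_nm Physical Gaussian SD of the emitter (0 = point
#'   source; > 0 for extended organelles).
#' @return Object of class `optics_model`.
#' @export
optics_model <- function(sigma_psf_nm = 112, photons_per_frame = 5000,
                         background_counts = 10, read_noise_sd = 2,
                         object_sigma_nm = 0) {
  assert_number(sigma_psf_nm, "sigma_psf_nm", 0, strict = TRUE)
  assert_number(photons_per_frame, "photons_per_frame", 0, strict = TRUE)
  assert_number(background_counts, "background_counts", 0)
  assert_number(read_noise_sd, "read_noise_sd", 0)
  assert_number(object_sigma_nm, "object_sigma_nm", 0)
  structure(list(sigma_psf_nm = sigma_psf_nm,
                 photons_per_frame = photons_per_frame,
                 background_counts = background_counts,
                 read_noise_sd = read_noise_sd,
                 object_sigma_nm = object_sigma_nm),
            class = "optics_model")
}

# Position(s) along a polyline at arc length s (um); s clamped to [0, L].
branch_point <- function(branch, s) {
  seg <- diff(branch)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  idx <- pmax(findInterval(s, cum, rightmost.closed = TRUE), 1)
  idx <- pmin(idx, nrow(branch) - 1)
  frac <- (s - cum[idx]) / len[idx]
  cbind(x = branch[idx, 1] + frac * seg[idx, 1],
        y = branch[idx, 2] + frac * seg[idx, 2])
}

branch_length <- function(branch) sum(sqrt(rowSums(diff(branch)^2)))

# One straight horizontal lane per particle, evenly spaced inside the FoV.
default_lanes <- function(n, geometry, margin_um = 1, lane_offset_um = 0) {
  ext <- fov_extent_um(geometry)
  ys <- if (n == 1) mean(c(margin_um, ext["height_um"] - margin_um)) else
    seq(margin_um, ext["height_um"] - margin_um, length.out = n)
  ys <- ys + lane_offset_um
  ys <- pmin(pmax(ys, 0.2), ext["height_um"] - 0.2)
  lapply(ys, function(y) {
    cbind(c(margin_um, ext["width_um"] - margin_um), c(y, y))
  })
}

# go/stop state per frame; TRUE = go during [t, t+1).
sim_states <- function(T, dt, go_s, stop_s, p_stop) {
  if (p_stop <= 0) return(rep(TRUE, T))
  states <- logical(0)
  cur <- runif(1) < go_s / (go_s + stop_s)
  while (length(states) < T) {
    dur <- rexp(1, rate = 1 / (if (cur) go_s else stop_s))
    k <- max(1L, as.integer(round(dur / dt)))
    states <- c(states, rep(cur, k))
    cur <- if (cur) runif(1) >= p_stop else TRUE
  }
  states[seq_len(T)]
}

#' Simulate ground-truth intermittent motion
#'
#' Generates per-frame true positions and go/stop phase labels for
#' `n_particles` cargoes. Moving particles start at a uniform arc length in
#' the first half of their branch and leave the simulation when they reach
#' the branch end (their observation simply stops, as a cargo leaving the
#' field of view); static particles sit at a uniform position for the whole
#' video. Identical seeds give identical output.
#'
#' @param model A [motion_model()].
#' @param geometry An [acquisition_geometry()].
#' @param n_particles Number of particles.
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param lane_offset_um Vertical shift applied to auto-generated lanes
#'   (used to interleave independent particle sets).
#' @return Object of class `ground_truth`: list with `positions` (data frame
#'   `particle`, `frame`, `x_um`, `y_um`, `phase`, `moving`), `particles`
#'   (per-particle parameters), `moving_fraction`, `model`, `geometry`.
#' @export
simulate_motion <- function(model, geometry, n_particles, seed = NULL,
                            lane_offset_um = 0) {
  stopifnot(inherits(model, "motion_model"),
            inherits(geometry, "acquisition_geometry"))
  assert_number(n_particles, "n_particles", 0)
  with_seed(seed, {
    T <- n_frames(geometry)
    dt <- 1 / geometry$frame_rate_hz
    ext <- fov_extent_um(geometry)
    branches <- if (is.null(model$branch)) {
      default_lanes(n_particles, geometry, lane_offset_um = lane_offset_um)
    } else {
      b <- model$branch
      if (any(b[, 1] < 0 | b[, 1] > ext["width_um"] |
              b[, 2] < 0 | b[, 2] > ext["height_um"])) {
        stop("geometry error: branch lies outside the field of view",
             call. = FALSE)
      }
      rep(list(b), n_particles)
    }
    n_moving <- round(model$p_moving * n_particles)
    moving <- rep(FALSE, n_particles)
    if (n_moving > 0) moving[sample.int(n_particles, n_moving)] <- TRUE

    jit_um <- model$jitter_sd_nm / 1000
    pos_list <- vector("list", n_particles)
    part_rows <- vector("list", n_particles)
    for (i in seq_len(n_particles)) {
      br <- branches[[i]]
      L <- branch_length(br)
      if (moving[i]) {
        start <- runif(1, 0, 0.5 * L)
        states <- sim_states(T, dt, model$go_duration_s,
                             model$stop_duration_s, model$p_stop)
        arc <- start + c(0, cumsum(model$v_go_um_s * dt * states[-T]))
        keep <- arc <= L
        if (!all(keep)) keep <- seq_along(arc) < which(!keep)[1]
        arc <- arc[keep]
        states <- states[keep]
      } else {
        start <- runif(1, 0, L)
        arc <- rep(start, T)
        states <- rep(FALSE, T)
      }
      nf <- length(arc)
      xy <- branch_point(br, arc)
      xy <- xy + matrix(rnorm(2 * nf, 0, jit_um), ncol = 2)
      pos_list[[i]] <- data.frame(
        particle = i, frame = seq_len(nf) - 1L,
        x_um = xy[, 1], y_um = xy[, 2],
        phase = ifelse(states, "go", "stop"),
        moving = moving[i], stringsAsFactors = FALSE)
      part_rows[[i]] <- data.frame(
        particle = i, moving = moving[i], start_arc_um = start,
        branch_length_um = L, n_frames = nf,
        v_go_um_s = model$v_go_um_s, go_duration_s = model$go_duration_s,
        stop_duration_s = model$stop_duration_s, stringsAsFactors = FALSE)
    }
    structure(list(
      positions = do.call(rbind, pos_list) %||% data.frame(),
      particles = do.call(rbind, part_rows) %||% data.frame(),
      moving_fraction = if (n_particles > 0) n_moving / n_particles else NA_real_,
      model = model, geometry = geometry, n_particles = n_particles
    ), class = "ground_truth")
  })
}

#' Convert ground truth to a trajectory table
#'
#' Maps true positions (um) to pixel coordinates, optionally adding Gaussian
#' localization noise, producing a table interchangeable with tracker output.
#'
#' @param truth A `ground_truth` from [simulate_motion()].
#' @param loc_noise_nm SD of localization noise added per coordinate (nm).
#' @param channel,condition,fov_id Annotation columns.
#' @param sigma_nm Value for the `sigma_px` column (fitted-width stand-in),
#'   in nm.
#' @param seed Optional seed for the noise.
#' @return Trajectory table (see [empty_trajectories()]) with extra columns
#'   `phase` and `moving` carrying the truth labels.
#' @export
truth_to_trajectories <- function(truth, loc_noise_nm = 0, channel = "red",
                                  condition = "sim", fov_id = "fov1",
                                  sigma_nm = 112, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  pos <- truth$positions
  if (nrow(pos) == 0) return(empty_trajectories())
  geometry <- truth$geometry
  with_seed(seed, {
    x_px <- um_to_px(pos$x_um, geometry)
    y_px <- um_to_px(pos$y_um, geometry)
    if (loc_noise_nm > 0) {
      x_px <- x_px + rnorm(nrow(pos), 0, loc_noise_nm / geometry$pixel_size_nm)
      y_px <- y_px + rnorm(nrow(pos), 0, loc_noise_nm / geometry$pixel_size_nm)
    }
    data.frame(fov_id = fov_id, condition = condition, channel = channel,
               particle_id = pos$particle, frame = pos$frame,
               x_px = x_px, y_px = y_px,
               sigma_px = sigma_nm / geometry$pixel_size_nm,
               intensity = 1, background = 0,
               phase = pos$phase, moving = pos$moving,
               stringsAsFactors = FALSE)
  })
}

#' Render a ground truth as a fluorescence video
#'
#' Each emitter becomes a pixel-integrated 2-D Gaussian of SD
#' `sqrt(sigma_psf_nm^2 + object_sigma_nm^2)` carrying `photons_per_frame`
#' expected counts; pixel values are Poisson draws over signal plus
#' background, plus Gaussian read noise (disabled with `noise = FALSE`).
#'
#' @param truth A `ground_truth`.
#' @param optics An [optics_model()].
#' @param geometry An [acquisition_geometry()].
#' @param seed Optional noise seed.
#' @param frames Optional 0-based frame indices to render (default: all
#'   frames of the geometry); use chunks to bound memory on long videos.
#' @param noise Render photon and read noise (`TRUE`) or the noiseless
#'   expectation (`FALSE`).
#' @return 3-D array `(frame, row, column)` of counts.
#' @export
render_video <- function(truth, optics, geometry = truth$geometry,
                         seed = NULL, frames = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(optics, "optics_model"))
  if (is.null(frames)) frames <- seq_len(n_frames(geometry)) - 1L
  h <- if (geometry$dual_view) geometry$view_height_px else geometry$sensor_height_px
  w <- geometry$sensor_width_px
  sigma_px <- sqrt(optics$sigma_psf_nm^2 + optics$object_sigma_nm^2) /
    geometry$pixel_size_nm
  pos <- truth$positions
  video <- array(0, dim = c(length(frames), h, w))
  with_seed(seed, {
    for (k in seq_along(frames)) {
      sel <- pos$frame == frames[k]
      xs <- um_to_px(pos$x_um[sel], geometry)
      ys <- um_to_px(pos$y_um[sel], geometry)
      expected <- render_spots_cpp(h, w, xs, ys,
                                   rep(sigma_px, sum(sel)),
                                   rep(optics$photons_per_frame, sum(sel)),
                                   optics$background_counts)
      if (noise) {
        counts <- rpois(length(expected), pmax(expected, 0))
        if (optics$read_noise_sd > 0) {
          counts <- counts + rnorm(length(counts), 0, optics$read_noise_sd)
        }
        video[k, , ] <- pmax(matrix(counts, h, w), 0)
      } else {
        video[k, , ] <- expected
      }
    }
  })
  video
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes the rendered video stack (TIFF), the ground-truth trajectory table
#' and per-particle plus per-FoV truth summaries.
#'
#' @param model A [motion_model()].
#' @param optics An [optics_model()].
#' @param geometry An [acquisition_geometry()].
#' @param n_particles Number of particles.
#' @param seed Integer seed.
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with file `paths` and the `truth` object.
#' @export
generate_dataset <- function(model, optics, geometry, n_particles, seed,
                             out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("I/O error: directory not writable: ", out_dir, call. = FALSE)
  }
  truth <- simulate_motion(model, geometry, n_particles, seed = seed)
  video <- render_video(truth, optics, geometry, seed = seed + 1L)
  paths <- list(video = file.path(out_dir, "video.tif"),
                trajectories = file.path(out_dir, "truth_trajectories.csv"),
                particles = file.path(out_dir, "truth_particles.csv"),
                fov = file.path(out_dir, "truth_fov.csv"))
  write_video_stack(video, paths$video)
  write_trajectories(
    truth_to_trajectories(truth, sigma_nm = sqrt(optics$sigma_psf_nm^2 +
                                                   optics$object_sigma_nm^2)),
    paths$trajectories)
  write.table(truth$particles, paths$particles, sep = ",", row.names = FALSE,
              quote = TRUE)
  write.table(data.frame(n_particles = n_particles,
                         n_moving = sum(truth$particles$moving %||% logical(0)),
                         moving_fraction = truth$moving_fraction),
              paths$fov, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Simulate a two-channel dataset with planted colocalization
#'
#' Green-channel particles follow `model`; a fraction `coloc_fraction` of the
#' *moving* green particles receives a red partner that follows the same
#' path at a small lateral offset (independent localization noise), while
#' `n_red_distractor` independent red particles move on interleaved lanes.
#' For clean planted truth the green lane spacing should exceed twice the
#' colocalization distance criterion.
#'
#' @param model A [motion_model()] for the green channel (and distractors).
#' @param geometry An [acquisition_geometry()].
#' @param n_green Number of green particles.
#' @param coloc_fraction Planted fraction of moving green particles with a
#'   red partner.
#' @param n_red_distractor Independent red particles.
#' @param seed Integer seed.
#' @param loc_noise_nm Localization noise added to both channels (nm).
#' @param partner_offset_nm Lateral offset of the red partner path (nm).
#' @return List `green`, `red` (trajectory tables in one coordinate frame),
#'   `truth` (planted fraction and ids), `geometry`.
#' @export
simulate_two_channel <- function(model, geometry, n_green, coloc_fraction,
                                 n_red_distractor, seed = NULL,
                                 loc_noise_nm = 10, partner_offset_nm = 80) {
  assert_number(coloc_fraction, "coloc_fraction", 0)
  if (coloc_fraction > 1) {
    stop("validation error: coloc_fraction must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    green_truth <- simulate_motion(model, geometry, n_green)
    green <- truth_to_trajectories(green_truth, loc_noise_nm = loc_noise_nm,
                                   channel = "green")
    movers <- green_truth$particles$particle[green_truth$particles$moving]
    n_coloc <- round(coloc_fraction * length(movers))
    chosen <- if (n_coloc > 0) sort(sample(movers, n_coloc)) else integer(0)

    # red partners: same path, lateral offset, independent localization noise
    partner_rows <- green[green$particle_id %in% chosen, , drop = FALSE]
    if (nrow(partner_rows) > 0) {
      pos <- green_truth$positions
      pos <- pos[pos$particle %in% chosen, , drop = FALSE]
      off_px <- partner_offset_nm / geometry$pixel_size_nm
      noise_px <- loc_noise_nm / geometry$pixel_size_nm
      partners <- data.frame(
        fov_id = "fov1", condition = unique(green$condition)[1],
        channel = "red",
        particle_id = match(pos$particle, chosen),
        frame = pos$frame,
        x_px = um_to_px(pos$x_um, geometry) + rnorm(nrow(pos), 0, noise_px),
        y_px = um_to_px(pos$y_um, geometry) + off_px +
          rnorm(nrow(pos), 0, noise_px),
        sigma_px = 112 / geometry$pixel_size_nm, intensity = 1,
        background = 0, stringsAsFactors = FALSE)
    } else {
      partners <- empty_trajectories()
    }

    # independent distractors on interleaved lanes
    ext <- fov_extent_um(geometry)
    spacing <- if (n_green > 1) (ext["height_um"] - 2) / (n_green - 1) else 1
    distr_truth <- simulate_motion(model, geometry, n_red_distractor,
                                   lane_offset_um = spacing / 2)
    distr <- truth_to_trajectories(distr_truth, loc_noise_nm = loc_noise_nm,
                                   channel = "red")
    if (nrow(distr) > 0) distr$particle_id <- distr$particle_id + n_coloc
    keep <- intersect(names(partners), names(distr))
    red <- rbind(partners[keep], distr[keep])

    list(green = green, red = red,
         truth = list(coloc_fraction = if (length(movers) > 0)
                        n_coloc / length(movers) else NA_real_,
                      colocalized_green = chosen,
                      n_moving_green = length(movers),
                      green_truth = green_truth),
         geometry = geometry)
  })
}
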