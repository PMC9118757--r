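# Small geometries and trajectory builders shared across tests.

tiny_geom <- function(width = 64, height = 64, duration_s = 5, ...) {
  acquisition_geometry(sensor_width_px = width, sensor_height_px = height,
                       duration_s = duration_s, ...)
}

# Trajectory table from bare coordinates (single particle).
make_traj <- function(x_px, y_px, frame = seq_along(x_px) - 1L,
                      particle_id = 1L, channel = "red") {
  data.frame(fov_id = "fov1", condition = "none", channel = channel,
             particle_id = particle_id, frame = frame,
             x_px = x_px, y_px = y_px, sigma_px = 1.4, intensity = 1000,
             background = 10, stringsAsFactors = FALSE)
}

# Straight run: `n` spots advancing `step_px` per frame along x.
straight_traj <- function(n, step_px = 0.625, y = 10, ...) {
  make_traj(x_px = 5 + step_px * (seq_len(n) - 1), y_px = rep(y, n), ...)
}

# Stationary particle (identical coordinates each frame).
static_traj <- function(n, x = 10, y = 10, ...) {
  make_traj(x_px = rep(x, n), y_px = rep(y, n), ...)
}

random_trajectories_table <- function(n_tracks, n_frames = 60) {
  do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    tr <- random_gostop_traj(n_frames)
    tr$particle_id <- i
    make_traj(tr$x_px, tr$y_px, frame = tr$frame, particle_id = i)
  }))
}
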