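render_frame <- function(x, y, sigma_px = 1.4, photons = 5000, bg = 10,
                         size = 64, noisy = TRUE, seed = 1) {
  n <- length(x)
  img <- cargotrack:::render_spots_cpp(size, size, x, y,
                                       rep(sigma_px, n), rep(photons, n), bg)
  if (noisy) {
    set.seed(seed)
    img <- matrix(rpois(length(img), img) + rnorm(length(img), 0, 2),
                  nrow(img), ncol(img))
  }
  img
}

test_that("pure-noise frames yield no detections above the mass floor", {
  set.seed(3)
  frame <- matrix(rpois(64 * 64, 10) + rnorm(64 * 64, 0, 2), 64, 64)
  sp <- locate_spots(frame, detection_params(min_mass = 500))
  expect_equal(nrow(sp), 0)
})

test_that("a bright spot is localized to sub-pixel accuracy", {
  frame <- render_frame(20.3, 41.7, seed = 9)
  sp <- locate_spots(frame, detection_params(min_mass = 1000))
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$x_px - 20.3)^2 + (sp$y_px - 41.7)^2), 0.15)
  expect_gt(sp$intensity, 3000)
})

test_that("well-separated spots give exactly one detection each", {
  frame <- render_frame(c(15, 35), c(20, 40), seed = 5)
  sp <- locate_spots(frame, detection_params(min_mass = 1000))
  expect_equal(nrow(sp), 2)
})

test_that("detections respect the minimum separation", {
  # two emitters 3 px apart merge into a single reported spot
  frame <- render_frame(c(30, 33), c(30, 30), seed = 7)
  sp <- locate_spots(frame, detection_params(min_mass = 500))
  expect_equal(nrow(sp), 1)
})

test_that("localization error is small at high SNR and grows as photons drop", {
  rmse_at <- function(photons) {
    errs <- vapply(1:40, function(k) {
      x0 <- 30 + runif(1, -0.5, 0.5)
      y0 <- 30 + runif(1, -0.5, 0.5)
      frame <- render_frame(x0, y0, photons = photons, seed = 100 + k)
      sp <- locate_spots(frame, detection_params(min_mass = photons / 20))
      if (nrow(sp) == 0) return(NA_real_)
      sp <- sp[which.max(sp$intensity), ]
      (sp$x_px - x0)^2 + (sp$y_px - y0)^2
    }, numeric(1))
    sqrt(mean(errs, na.rm = TRUE))
  }
  set.seed(17)
  r_hi <- rmse_at(5000)
  r_mid <- rmse_at(800)
  r_lo <- rmse_at(200)
  expect_lt(r_hi, 0.2)
  expect_lt(r_hi, r_mid)
  expect_lt(r_mid, r_lo)
})

test_that("a drifting spot links into a single trajectory", {
  spots <- data.frame(frame = 0:99, x_px = 10 + (0:99) * 1, y_px = 20)
  linked <- link_spots(spots, detection_params(max_displacement_px = 3))
  expect_equal(length(unique(linked$particle_id)), 1)
  expect_equal(nrow(linked), 100)
})

test_that("two static spots keep distinct stable ids", {
  spots <- rbind(data.frame(frame = rep(0:49, each = 2),
                            x_px = rep(c(10, 40), 50),
                            y_px = rep(c(10, 40), 50)))
  linked <- link_spots(spots, detection_params(max_displacement_px = 5))
  expect_equal(length(unique(linked$particle_id)), 2)
  by_id <- split(linked, linked$particle_id)
  for (tr in by_id) {
    expect_equal(length(unique(tr$x_px)), 1)  # no id ever swaps position
    expect_equal(nrow(tr), 50)
  }
})

test_that("gap memory bridges exactly as configured", {
  frames <- c(0:4, 6:10)  # frame 5 missing
  spots <- data.frame(frame = frames, x_px = 10 + frames * 0.5, y_px = 5)
  with_mem <- link_spots(spots, detection_params(max_displacement_px = 3,
                                                 memory_frames = 1))
  expect_equal(length(unique(with_mem$particle_id)), 1)
  without <- link_spots(spots, detection_params(max_displacement_px = 3,
                                                memory_frames = 0))
  expect_equal(length(unique(without$particle_id)), 2)
})

test_that("linking minimizes total squared displacement, not greedy order", {
  # tracks a1 = 0, a2 = 2.05; new spots b1 = 1, b2 = -1.1 (radius 2.5).
  # greedy would take the single cheapest link a1-b1 (d2 = 1) and strand b2
  # as a new track (penalty 6.25); the optimum is a1-b2 + a2-b1
  # (1.21 + 1.1025 = 2.31).
  spots <- data.frame(
    frame = c(0, 0, 1, 1),
    x_px = c(0, 2.05, 1, -1.1),
    y_px = 0)
  linked <- link_spots(spots, detection_params(max_displacement_px = 2.5))
  id_of <- function(x, f) linked$particle_id[linked$x_px == x & linked$frame == f]
  expect_equal(id_of(-1.1, 1), id_of(0, 0))
  expect_equal(id_of(1, 1), id_of(2.05, 0))
  expect_equal(length(unique(linked$particle_id)), 2)
})

test_that("linking is invariant to spot order within frames", {
  set.seed(23)
  tab <- random_trajectories_table(6, n_frames = 40)
  spots <- tab[c("frame", "x_px", "y_px")]
  a <- link_spots(spots, detection_params(max_displacement_px = 3))
  b <- link_spots(spots[sample(nrow(spots)), ], detection_params(max_displacement_px = 3))
  canon <- function(d) {
    key <- paste(d$frame, round(d$x_px, 6), round(d$y_px, 6))
    parts <- split(key, d$particle_id)
    sort(vapply(parts, function(p) paste(sort(p), collapse = ";"), ""))
  }
  expect_identical(unname(canon(a)), unname(canon(b)))
})

test_that("short trajectories are filtered by spot count", {
  lens <- c(10, 49, 50, 200)
  tab <- do.call(rbind, lapply(seq_along(lens), function(i) {
    straight_traj(lens[i], particle_id = i)
  }))
  kept <- filter_trajectories(tab, detection_params(min_track_frames = 50))
  expect_equal(attr(kept, "n_kept"), 2)
  expect_equal(attr(kept, "n_dropped"), 2)
  expect_setequal(unique(kept$particle_id), c(3, 4))

  all_kept <- filter_trajectories(tab, 10)
  expect_equal(attr(all_kept, "n_dropped"), 0)
  expect_error(filter_trajectories(tab, -1), "validation error")
})

test_that("tracking recovers simulated particles as single clean tracks", {
  geom <- acquisition_geometry(sensor_width_px = 200, sensor_height_px = 160,
                               duration_s = 10)
  mm <- motion_model(p_moving = 0.5)
  truth <- simulate_motion(mm, geom, 10, seed = 31)
  video <- render_video(truth, optics_model(), geom, seed = 32)
  traj <- track_video(video, detection_params(min_mass = 1000, threshold = 25))
  expect_equal(length(unique(traj$particle_id)), 10)
  # localization against truth: match first frame spots to truth positions
  t0 <- truth$positions[truth$positions$frame == 0, ]
  s0 <- traj[traj$frame == 0, ]
  for (i in seq_len(nrow(t0))) {
    d <- sqrt((s0$x_px - t0$x_um[i] * 1000 / 80)^2 +
                (s0$y_px - t0$y_um[i] * 1000 / 80)^2)
    expect_lt(min(d), 0.2)
  }
})
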