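test_that("simulate_motion is deterministic under a seed", {
  geom <- tiny_geom(200, 100, duration_s = 10)
  mm <- motion_model()
  a <- simulate_motion(mm, geom, 10, seed = 7)
  b <- simulate_motion(mm, geom, 10, seed = 7)
  expect_identical(a$positions, b$positions)
  expect_identical(a$particles, b$particles)
})

test_that("degenerate no-stop model yields one go phase covering all frames", {
  geom <- tiny_geom(400, 50, duration_s = 5)
  mm <- motion_model(p_stop = 0, p_moving = 1, jitter_sd_nm = 0)
  tr <- simulate_motion(mm, geom, 3, seed = 1)
  for (p in split(tr$positions, tr$positions$particle)) {
    expect_true(all(p$phase == "go"))
  }
})

test_that("go-phase step size is v / frame_rate", {
  geom <- tiny_geom(500, 50, duration_s = 5)
  mm <- motion_model(v_go_um_s = 1, p_stop = 0, p_moving = 1, jitter_sd_nm = 0)
  tr <- simulate_motion(mm, geom, 1, seed = 3)
  p <- tr$positions
  steps <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)
  expect_equal(steps, rep(0.05, nrow(p) - 1), tolerance = 1e-12)
})

test_that("planted moving fraction is exact by construction", {
  geom <- tiny_geom(300, 300, duration_s = 2)
  tr <- simulate_motion(motion_model(p_moving = 0.3), geom, 100, seed = 5)
  expect_equal(sum(tr$particles$moving), 30)
  expect_equal(tr$moving_fraction, 0.30)
})

test_that("phase durations pooled over particles match the exponential means", {
  geom <- acquisition_geometry(sensor_width_px = 2000, sensor_height_px = 600,
                               duration_s = 60)
  mm <- motion_model(p_moving = 1, go_duration_s = 2, stop_duration_s = 1)
  tr <- simulate_motion(mm, geom, 40, seed = 8)
  # interior phases only (edge phases are censored by the observation window)
  durs <- lapply(split(tr$positions, tr$positions$particle), function(p) {
    r <- rle(p$phase)
    if (length(r$lengths) < 3) return(NULL)
    keep <- 2:(length(r$lengths) - 1)
    data.frame(kind = r$values[keep], s = r$lengths[keep] / 20)
  })
  durs <- do.call(rbind, durs)
  expect_equal(mean(durs$s[durs$kind == "go"]), 2, tolerance = 0.15)
  expect_equal(mean(durs$s[durs$kind == "stop"]), 1, tolerance = 0.15)
})

test_that("branch outside the FoV is a geometry error", {
  geom <- tiny_geom(100, 100, duration_s = 1)
  bad <- motion_model(branch = cbind(c(0, 50), c(1, 1)))  # 50 um > 8 um FoV
  expect_error(simulate_motion(bad, geom, 1, seed = 1), "geometry error")
})

test_that("rendered spot width follows the quadrature law", {
  geom <- tiny_geom(48, 48, duration_s = 1 / 20)
  mm <- motion_model(p_moving = 0, jitter_sd_nm = 0,
                     branch = cbind(c(1.8, 2.0), c(1.9, 1.9)))
  tr <- simulate_motion(mm, geom, 1, seed = 2)
  for (obj in c(0, 100, 200)) {
    opt <- optics_model(object_sigma_nm = obj, photons_per_frame = 20000)
    img <- render_video(tr, opt, geom, noise = FALSE)[1, , ]
    sp <- locate_spots(img, detection_params(spot_diameter_px = 13,
                                             min_mass = 1000))
    expect_equal(nrow(sp), 1)
    expected_nm <- sqrt(112^2 + obj^2)
    expect_equal(sp$sigma_px * 80, expected_nm, tolerance = 0.02)
  }
})

test_that("zero emitters render as pure background", {
  geom <- tiny_geom(32, 32, duration_s = 0.25)
  tr <- simulate_motion(motion_model(), geom, 0, seed = 1)
  opt <- optics_model(background_counts = 10)
  clean <- render_video(tr, opt, geom, noise = FALSE)
  expect_true(all(clean == 10))
  noisy <- render_video(tr, opt, geom, seed = 4, noise = TRUE)
  expect_equal(mean(noisy), 10, tolerance = 0.05)
})

test_that("mean of many noisy renders converges to the noiseless expectation", {
  geom <- tiny_geom(24, 24, duration_s = 1 / 20)
  mm <- motion_model(p_moving = 0, jitter_sd_nm = 0,
                     branch = cbind(c(0.9, 1.0), c(0.95, 0.95)))
  tr <- simulate_motion(mm, geom, 1, seed = 6)
  opt <- optics_model(photons_per_frame = 2000, read_noise_sd = 1)
  expected <- render_video(tr, opt, geom, noise = FALSE)[1, , ]
  acc <- matrix(0, 24, 24)
  n_rep <- 300
  for (k in seq_len(n_rep)) {
    acc <- acc + render_video(tr, opt, geom, seed = 1000 + k)[1, , ]
  }
  avg <- acc / n_rep
  # per-pixel: mean within 6 standard errors; globally: tight agreement
  se <- sqrt(pmax(expected, 1) / n_rep) + 1 / sqrt(n_rep)
  expect_true(all(abs(avg - expected) < 6 * se))
  expect_equal(mean(avg), mean(expected), tolerance = 0.01)
})

test_that("generate_dataset writes a consistent bundle", {
  out <- withr::local_tempdir()
  geom <- tiny_geom(150, 100, duration_s = 3)
  res <- generate_dataset(motion_model(p_moving = 0.3), optics_model(),
                          geom, 10, seed = 12, out_dir = out)
  expect_true(all(file.exists(unlist(res$paths))))
  # truth tables carry the extra phase/moving columns, which the reader
  # flags but keeps
  expect_warning(truth_tab <- read_trajectories(res$paths$trajectories),
                 "phase")
  expect_equal(sort(unique(truth_tab$particle_id)), 1:10)
  fov <- read.csv(res$paths$fov)
  expect_equal(fov$moving_fraction, 0.30)
  video <- read_video_stack(res$paths$video)
  expect_identical(dim(video), c(n_frames(geom), 100L, 150L))

  # n = 0: valid empty truth, background-only video
  res0 <- generate_dataset(motion_model(), optics_model(), tiny_geom(32, 32, 0.25),
                           0, seed = 1, out_dir = file.path(out, "empty"))
  expect_equal(nrow(read_trajectories(res0$paths$trajectories)), 0)
  expect_equal(ncol(read_video_stack(res0$paths$video)), 32)
  v0 <- read_video_stack(res0$paths$video)
  expect_equal(mean(v0), optics_model()$background_counts, tolerance = 0.1)
})

test_that("two-channel simulation plants the colocalized fraction exactly", {
  geom <- acquisition_geometry(sensor_width_px = 300, sensor_height_px = 400,
                               duration_s = 10)
  mm <- motion_model(p_moving = 1)
  sim <- simulate_two_channel(mm, geom, n_green = 30, coloc_fraction = 0.4,
                              n_red_distractor = 10, seed = 21)
  expect_equal(sim$truth$coloc_fraction, 0.40)
  expect_equal(length(sim$truth$colocalized_green), 12)
  expect_setequal(unique(sim$green$channel), "green")
  expect_setequal(unique(sim$red$channel), "red")
})
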