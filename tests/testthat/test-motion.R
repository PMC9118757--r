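geom80 <- acquisition_geometry()  # 80 nm px, 20 Hz

test_that("confinement ratio matches closed-form cases", {
  # straight constant-velocity line: ratio 1 everywhere
  tr <- straight_traj(41)
  expect_equal(confinement_ratio_profile(tr, phase_params(window_frames = 9)),
               rep(1, 41))

  # out-and-back inside one window: 0 at the turning point
  xs <- c(0:5, 4:0)
  tr2 <- make_traj(xs, rep(0, 11))
  r2 <- confinement_ratio_profile(tr2, phase_params(window_frames = 11))
  expect_equal(r2[6], 0)

  # right angle over a 3-frame window: sqrt(2) / 2
  tr3 <- make_traj(c(0, 1, 1), c(0, 0, 1))
  r3 <- confinement_ratio_profile(tr3, phase_params(window_frames = 3))
  expect_equal(r3[2], sqrt(2) / 2)

  # zero-path window yields 0
  expect_equal(confinement_ratio_profile(static_traj(5), phase_params()),
               rep(0, 5))
})

test_that("confinement ratio equals the reference implementation", {
  set.seed(101)
  for (rep_i in 1:30) {
    tr <- random_gostop_traj(sample(10:80, 1))
    for (w in c(3, 5, 9, 21)) {
      expect_equal(confinement_ratio_profile(tr, phase_params(window_frames = w)),
                   ref_confinement(tr$x_px, tr$y_px, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("ratio is scale-invariant; resampling preserves velocity", {
  set.seed(7)
  tr <- random_gostop_traj(60)
  pp <- phase_params()
  tr_scaled <- tr
  tr_scaled$x_px <- tr$x_px * 3.2
  tr_scaled$y_px <- tr$y_px * 3.2
  expect_equal(confinement_ratio_profile(tr_scaled, pp),
               confinement_ratio_profile(tr, pp), tolerance = 1e-12)

  # the same physical straight run sampled at 20 vs 40 Hz
  g20 <- acquisition_geometry(frame_rate_hz = 20)
  g40 <- acquisition_geometry(frame_rate_hz = 40)
  run20 <- straight_traj(100, step_px = 0.625)           # 1 um/s at 20 Hz
  run40 <- straight_traj(199, step_px = 0.3125)          # same span at 40 Hz
  tp20 <- transport_parameters(run20, parse_phases(run20, pp, g20), g20)
  tp40 <- transport_parameters(run40, parse_phases(run40, pp, g40), g40)
  expect_equal(tp20$velocity_um_s, 1, tolerance = 1e-9)
  expect_equal(tp40$velocity_um_s, tp20$velocity_um_s, tolerance = 1e-9)
  expect_equal(tp40$duration_s, tp20$duration_s)
})

test_that("parse_phases handles pure regimes", {
  pp <- phase_params()
  run <- straight_traj(80)
  ph <- parse_phases(run, pp, geom80)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$kind, "go")
  expect_equal(ph$n_frames, 80)

  ph0 <- parse_phases(static_traj(60), pp, geom80)
  expect_equal(nrow(ph0), 1)
  expect_equal(ph0$kind, "stop")
})

test_that("phases partition every trajectory", {
  set.seed(33)
  pp <- phase_params()
  for (rep_i in 1:20) {
    tr <- random_gostop_traj(sample(12:120, 1))
    ph <- parse_phases(tr, pp, geom80)
    expect_equal(sum(ph$n_frames), nrow(tr))
    expect_equal(ph$start_idx[1], 1)
    expect_equal(ph$end_idx[nrow(ph)], nrow(tr))
    if (nrow(ph) > 1) {
      expect_equal(ph$start_idx[-1], ph$end_idx[-nrow(ph)] + 1)
      expect_true(all(ph$kind[-1] != ph$kind[-nrow(ph)]))
    }
    expect_equal(sum(ph$duration_s), (nrow(tr) - 1) / geom80$frame_rate_hz)
    expect_true(all(ph$net_displacement_um <= ph$path_length_um + 1e-12))
    expect_true(all(ph$n_frames >= min(pp$min_phase_frames, nrow(tr))))
  }
})

test_that("parse_phases agrees with the brute-force reference frame-for-frame", {
  set.seed(55)
  pp <- phase_params()
  for (rep_i in 1:200) {
    tr <- random_gostop_traj(sample(10:90, 1))
    got <- phases_to_labels(parse_phases(tr, pp, geom80))
    want <- ref_parse_labels(tr$x_px, tr$y_px, pp$window_frames,
                             pp$confinement_threshold, pp$min_phase_frames)
    expect_identical(got, want)
  }
})

test_that("transport parameters reproduce the worked example", {
  # 10 um in 10 s of go, then a 5 s stop (15 s observed): v = 1 um/s,
  # run = 10 um, pausing time = 5 s, pausing frequency = 4 / min,
  # total = 10 um
  x_um <- c(0.05 * (0:200), rep(10, 100))
  tr <- make_traj(x_um * 1000 / 80, rep(0, 301))
  phases <- data.frame(kind = c("go", "stop"),
                       start_idx = c(1, 202), end_idx = c(201, 301),
                       start_frame = c(0, 201), end_frame = c(200, 300),
                       n_frames = c(201, 100), duration_s = c(10, 5),
                       path_length_um = c(10, 0),
                       net_displacement_um = c(10, 0))
  tp <- transport_parameters(tr, phases, geom80)
  expect_equal(tp$velocity_um_s, 1)
  expect_equal(tp$run_length_um, 10)
  expect_equal(tp$pausing_time_s, 5)
  expect_equal(tp$pausing_frequency_per_min, 4)
  expect_equal(tp$total_length_um, 10)
  expect_equal(tp$n_go, 1)
  expect_equal(tp$n_stop, 1)
})

test_that("all-stop trajectories have zero total length and defined frequency", {
  tr <- static_traj(120)
  ph <- parse_phases(tr, phase_params(), geom80)
  tp <- transport_parameters(tr, ph, geom80)
  expect_equal(tp$total_length_um, 0)
  expect_true(is.na(tp$velocity_um_s))
  expect_equal(tp$pausing_frequency_per_min, 1 / (119 / 20 / 60))
})

test_that("moving classification needs a 1 um directed go phase", {
  pp <- phase_params()
  run <- straight_traj(60)  # 59 steps x 50 nm = 2.95 um
  expect_true(classify_moving(run, parse_phases(run, pp, geom80), pp))
  stat <- static_traj(60)
  expect_false(classify_moving(stat, parse_phases(stat, pp, geom80), pp))
  # short run below the displacement floor
  short_run <- straight_traj(60, step_px = 0.1)  # 0.47 um net
  expect_false(classify_moving(short_run, parse_phases(short_run, pp, geom80), pp))
})

test_that("summarize_fov counts particles and movers", {
  tab <- rbind(
    do.call(rbind, lapply(1:3, function(i) straight_traj(80, particle_id = i,
                                                         y = 5 * i))),
    do.call(rbind, lapply(4:10, function(i) static_traj(80, particle_id = i,
                                                        y = 5 * i))))
  res <- summarize_fov(tab, geom80, phase_params())
  expect_equal(res$summary$n_particles, 10)
  expect_equal(res$summary$n_moving, 3)
  expect_equal(res$summary$moving_fraction, 0.3)
  expect_equal(nrow(res$parameters), 3)       # movers only
  expect_equal(nrow(res$trajectories), 10)

  empty <- summarize_fov(empty_trajectories(), geom80, phase_params())
  expect_equal(empty$summary$n_particles, 0)
  expect_true(is.na(empty$summary$moving_fraction))
})

test_that("parse_phases validates its input", {
  expect_error(parse_phases(static_traj(1), phase_params(), geom80),
               "2 spots")
  bad <- straight_traj(10)
  bad$frame[5] <- bad$frame[4]
  expect_error(parse_phases(bad, phase_params(), geom80), "increasing")
})

test_that("phase and parameter recovery on simulated truth trajectories", {
  geom <- acquisition_geometry(sensor_width_px = 1500, sensor_height_px = 400,
                               duration_s = 60)
  mm <- motion_model(p_moving = 1)
  truth <- simulate_motion(mm, geom, 15, seed = 71)
  tab <- truth_to_trajectories(truth, loc_noise_nm = 10, seed = 72)
  res <- analyze_trajectories(tab, geom, phase_params())
  expect_equal(nrow(res), 15)
  expect_true(all(res$moving))
  expect_equal(mean(res$velocity_um_s), 1, tolerance = 0.1)
  # go/stop boundaries land near the truth: compare pooled go fraction
  truth_go <- mean(truth$positions$phase == "go")
  got_go <- sum(res$total_length_um) / 1 / sum(res$duration_s)
  expect_equal(got_go, truth_go, tolerance = 0.1)
})
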