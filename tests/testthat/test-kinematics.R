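test_that("segmentation finds alternating interior-complete half-strokes", {
  fps <- 119.88; f <- 2
  t <- seq(0, 5.75 / f, by = 1 / fps)
  y <- sin(2 * pi * f * t)
  seg <- segment_wingbeats(y, fps, time = t)
  expect_identical(sum(seg$half_stroke == "upstroke"), 5L)
  expect_identical(sum(seg$half_stroke == "downstroke"), 5L)
  # strict alternation
  expect_true(all(seg$half_stroke[-1] != seg$half_stroke[-nrow(seg)]))
  # durations are half periods, elevations unit peak-to-trough
  expect_equal(seg$duration, rep(0.25, 10), tolerance = 1e-3)
  expect_equal(wing_excursion(seg), rep(2, 5), tolerance = 1e-3)
})

test_that("segmentation is robust to sub-prominence jitter", {
  fps <- 119.88
  t <- seq(0, 2.5, by = 1 / fps)
  y <- sin(2 * pi * 2.4 * t)
  set.seed(1)
  y_noisy <- smooth_series(y + rnorm(length(y), 0, 0.02), 0.999, time = t)
  clean_count <- nrow(segment_wingbeats(y, fps, time = t))
  noisy_count <- nrow(segment_wingbeats(y_noisy, fps, time = t))
  expect_identical(noisy_count, clean_count)
  expect_error(segment_wingbeats(seq_len(200), fps), "no wingbeats")
})

test_that("wingbeat frequency follows both conventions", {
  fps <- 239.76
  t <- seq(0, 12.6 / 8, by = 1 / fps)
  seg <- segment_wingbeats(sin(2 * pi * 8 * t), fps, time = t)
  expect_equal(wingbeat_frequency(seg, "per_wingbeat"),
               rep(8, length(wingbeat_frequency(seg, "per_wingbeat"))),
               tolerance = 1e-3)
  expect_equal(wingbeat_frequency(seg, "per_flight"), 8, tolerance = 1e-3)
  # 12 complete wingbeats spanning 1.5 s -> 8 Hz
  tm <- diff(range(attr(seg, "extrema")$t[attr(seg, "extrema")$type == "min"]))
  expect_equal((sum(attr(seg, "extrema")$type == "min") - 1) / tm, 8,
               tolerance = 1e-3)
})

test_that("stroke-plane angle lands on the stated side of 90 degrees", {
  # purely vertical stroke
  r90 <- recover(clean_params(stroke_plane_beta = 90))
  expect_equal(r90$beta_deg, 90, tolerance = 0.2)
  # aerial convention: down-and-forward downstroke, beta < 90
  r79 <- recover(clean_params(fluid = "air", stroke_plane_beta = 79,
                              chord_alpha_up = 0, chord_alpha_down = 0,
                              wingbeat_freq_f = 8, speed_U = 16,
                              excursion_A = 0.3, frame_rate = 239.76))
  expect_equal(r79$beta_deg, 79, tolerance = 0.5)
  expect_lt(r79$beta_deg, 90)
  # aquatic convention: down-and-back downstroke, beta > 90
  r92 <- analyze_flight(generate_flight(synthetic_flight_params(
    stroke_plane_beta = 92, noise_sd = 1, head_bob_amp = 0.05, seed = 2)))
  expect_equal(r92$beta_deg, 92, tolerance = 2)
  expect_gt(r92$beta_deg, 90)
  # forward/down displacement of slope tan(79 deg) -> 79 degrees
  disp <- c(1 / tan(79 * pi / 180), -1)
  expect_equal(180 / pi * acos(disp[1] / sqrt(sum(disp^2))), 79, tolerance = 1e-9)
})

test_that("chord angle recovers mid-stroke values and pure geometry", {
  expect_equal(alcidkin:::angle_between(c(1, 0), c(1, 0)), 0)
  expect_equal(alcidkin:::angle_between(c(0, 1), c(1, 0)), 90)
  r <- recover(clean_params(chord_alpha_up = 40, chord_alpha_down = 50))
  expect_equal(r$alpha_up_deg, 40, tolerance = 2)
  expect_equal(r$alpha_down_deg, 50, tolerance = 2)
  rn <- analyze_flight(generate_flight(synthetic_flight_params(
    chord_alpha_up = 40, chord_alpha_down = 50, noise_sd = 1, seed = 4)))
  expect_equal(rn$alpha_up_deg, 40, tolerance = 2)
})

test_that("wingbeat amplitude is the angle subtended at the shoulder", {
  sh <- c(0, 0)
  expect_equal(wingbeat_amplitude_deg(sh, c(cos(pi / 4), sin(pi / 4)),
                                      c(cos(pi / 4), -sin(pi / 4))), 90)
  expect_equal(wingbeat_amplitude_deg(sh, c(cos(pi / 6), sin(pi / 6)),
                                      c(cos(pi / 6), -sin(pi / 6))), 60)
  expect_error(wingbeat_amplitude_deg(sh, c(0, 0), c(1, 0)), "zero-length")

  r <- recover(clean_params(view = "parallel", amplitude_deg = 100))
  expect_equal(r$amplitude_deg, 100, tolerance = 3)
})

test_that("stroke velocity is sweep over duration, with the 0.5/f shortcut", {
  expect_equal(stroke_velocity(90, 0.05), 1800)
  expect_equal(stroke_velocity(100, 0.2), 500)
  expect_equal(0.5 / 8, 0.0625)
  expect_error(stroke_velocity(90, 0), "> 0")

  tr <- generate_flight(clean_params(view = "parallel", amplitude_deg = 80))
  per <- analyze_flight(tr, params = analysis_params(stroke_velocity_mode = "per_stroke"))
  app <- analyze_flight(tr, params = analysis_params(stroke_velocity_mode = "approx"))
  expect_equal(per$stroke_vel_up / app$stroke_vel_up, 1, tolerance = 0.02)
  expect_equal(per$stroke_vel_down / app$stroke_vel_down, 1, tolerance = 0.02)
})

test_that("translational velocity is exact for rigid motion, pitch-corrected", {
  tr <- toy_track(vx = 2, bl = 200, fps = 119.88)   # 1.1988 BL/s
  res <- analyze_flight(tr)
  expect_equal(res$U_bls, 2 * 119.88 / 200, tolerance = 1e-4)
  expect_lt(res$U_sd_bls, 1e-3)

  # pure pitching about the midpoint, zero translation
  p <- clean_params(speed_U = 0, pitch_amp = 4)
  tr2 <- generate_flight(p)
  t <- track_time(tr2)
  bls <- smooth_series(body_length_series(tr2), 1e-4, time = t)
  st2 <- smooth_track(calibrate_to_body_lengths(tr2, bls))
  v <- translational_velocity(st2, "tail", pitch_correction = TRUE)
  expect_lt(abs(v$mean), 1e-3)
  v_raw <- translational_velocity(st2, "tail", pitch_correction = FALSE)
  expect_gt(mean(abs(v_raw$series - v$series)), 0)

  # murre-like flight: metric velocity within 2 percent
  cfg <- load_species_config()
  r3 <- recover(synthetic_flight_params(pitch_amp = 2, noise_sd = 0), config = cfg)
  expect_lt(abs(r3$U_ms - 1.63) / 1.63, 0.02)
})

test_that("Strouhal arithmetic, SD propagation and airspeed ranges", {
  expect_identical(strouhal(1, 1, 1), 1)
  expect_equal(strouhal(2.4, 0.122, 1.63), 0.1796, tolerance = 1e-3)
  expect_equal(strouhal(2.4, 0.122, 1.63),
               strouhal(2.4, 0.122 * 7, 1.63 * 7), tolerance = 1e-12)
  expect_error(strouhal(0, 1, 1), "> 0")

  expect_identical(strouhal_sd(2.4, 0, 1.63), 0)
  expect_equal(strouhal_sd(2.5, 0.01, 1.25), 0.02)
  # Monte-Carlo oracle: A ~ Normal, f and U fixed
  set.seed(42)
  draws <- strouhal(2.4, pmax(rnorm(1e5, 0.122, 0.01), 1e-6), 1.63)
  expect_equal(sd(draws), strouhal_sd(2.4, 0.01, 1.63), tolerance = 0.02)

  cfg <- load_species_config()
  rng <- strouhal_airspeed_range(9, 0.26, "horned_puffin", cfg)
  expect_equal(rng$st_low, 0.1255, tolerance = 1e-3)
  expect_equal(rng$st_high, 0.1677, tolerance = 1e-3)
  expect_lt(rng$st_low, rng$st_high)
  cfg$airspeed_low <- cfg$airspeed_high
  rng2 <- strouhal_airspeed_range(9, 0.26, "horned_puffin", cfg)
  expect_equal(rng2$st_low, rng2$st_high)
  expect_error(strouhal_airspeed_range(9, 0.26, "dodo", cfg), "not found")
})

test_that("St is invariant to frame-rate resampling and pixel scale", {
  st_at <- function(fps, px) {
    r <- recover(clean_params(frame_rate = fps, px_per_m = px))
    r$st
  }
  st_ref <- st_at(119.88, 1000)
  expect_equal(st_at(59.94, 1000), st_ref, tolerance = 0.01)
  expect_equal(st_at(29.97, 1000), st_ref, tolerance = 0.01)  # ~6 samples/half-stroke
  expect_equal(st_at(119.88, 250), st_ref, tolerance = 1e-4)
})

test_that("flights aggregate per wingbeat with zero SD when identical", {
  tr <- generate_flight(clean_params(n_wingbeats = 6))
  r <- analyze_flight(tr)
  expect_identical(r$n_wingbeats, 5)
  expect_lt(r$f_sd / r$f_hz, 1e-4)
  expect_lt(r$A_sd_bl / r$A_bl, 1e-3)
  expect_lt(r$st_sd / r$st, 1e-3)
})
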