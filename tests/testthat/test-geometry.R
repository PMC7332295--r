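test_that("descent angle is recovered from clean and perturbed tracks", {
  expect_equal(estimate_descent_angle(generate_flight(clean_params(descent_angle = 30))),
               30, tolerance = 1e-6)
  expect_equal(estimate_descent_angle(generate_flight(clean_params(descent_angle = 0))),
               0, tolerance = 1e-6)
  noisy <- generate_flight(synthetic_flight_params(
    descent_angle = 30, head_bob_amp = 0.05, noise_sd = 1, seed = 3))
  expect_equal(estimate_descent_angle(noisy), 30, tolerance = 1)
  still <- generate_flight(clean_params(speed_U = 0, excursion_A = 1e-4))
  still$data$eye_x[] <- 100; still$data$eye_y[] <- 50
  still$data$tail_x[] <- 0; still$data$tail_y[] <- 50
  expect_error(estimate_descent_angle(still), "zero net displacement")
})

test_that("flights classify by fluid and trajectory with an excluded gap", {
  expect_identical(classify_flight(5, "water"), "horizontal_aquatic")
  expect_identical(classify_flight(25, "water"), "descending_aquatic")
  expect_identical(classify_flight(15, "water"), "unclassified")
  expect_identical(classify_flight(15, "air"), "aerial")
  # total on [0, 90] x fluid
  for (a in seq(0, 90, by = 2.5)) {
    expect_true(classify_flight(a, "water") %in%
                  c("horizontal_aquatic", "descending_aquatic", "unclassified"))
    expect_identical(classify_flight(a, "air"), "aerial")
  }
})

test_that("path-frame rotation is an isometry that levels the mean path", {
  tr <- generate_flight(clean_params(descent_angle = 30))
  same <- rotate_to_path_frame(tr, 0)
  expect_equal(same$data, tr$data)

  rot <- rotate_to_path_frame(tr, 30)
  for (pair in list(c("eye", "tail"), c("wrist", "wingtip"), c("eye", "wrist"))) {
    d0 <- sqrt(rowSums((landmark_xy(tr, pair[1]) - landmark_xy(tr, pair[2]))^2))
    d1 <- sqrt(rowSums((landmark_xy(rot, pair[1]) - landmark_xy(rot, pair[2]))^2))
    expect_lt(max(abs(d1 - d0) / d0), 1e-9)
  }
  mid <- body_midpoint(rot)
  vy <- diff(mid[, 2]) * tr$frame_rate / (tr$ground_truth$body_length * 1000)
  expect_lt(abs(mean(vy)), 1e-6)   # BL/s
})

test_that("body length series reflects geometry and head movement", {
  tr <- generate_flight(clean_params())
  expect_equal(diff(range(body_length_series(tr))), 0, tolerance = 1e-9)

  d <- tibble::tibble(frame = 0:1, eye_x = c(0, 1), eye_y = c(0, 0),
                      tail_x = c(3, 4), tail_y = c(4, 4),
                      wrist_x = c(1, 1), wrist_y = c(2, 3))
  t345 <- landmark_track(d, frame_rate = 10)
  expect_equal(body_length_series(t345), c(5, 5))

  bob <- generate_flight(clean_params(head_bob_amp = 0.05))
  bl <- body_length_series(bob)
  expect_equal(dominant_frequency(bl, track_time(bob)), 2.4, tolerance = 0.05)

  bad <- t345
  bad$data$tail_x <- bad$data$eye_x
  bad$data$tail_y <- bad$data$eye_y
  expect_error(body_length_series(bad), "coincident")
})

test_that("smoothing spline reproduces constants and lines, flattens fast bob", {
  t <- (0:599) / 119.88
  for (p in c(1e-4, 0.01, 0.5)) {
    expect_equal(smooth_series(rep(3, 600), p, time = t), rep(3, 600),
                 tolerance = 1e-5)
    lin <- 2 + 0.5 * t
    expect_equal(smooth_series(lin, p, time = t), lin, tolerance = 1e-5)
  }
  mu <- 200
  y <- mu * (1 + 0.05 * sin(2 * pi * 2.4 * t))
  sm <- smooth_series(y, 1e-4, time = t)
  expect_lt(max(abs(sm - mu)) / mu, 0.01)
  expect_error(smooth_series(y, 0, time = t), "\\(0, 1\\]")
  expect_error(smooth_series(y, 1.5, time = t), "\\(0, 1\\]")
})

test_that("smoothing is monotone in p toward the data", {
  t <- (0:299) / 119.88
  y <- sin(2 * pi * 2.4 * t) + 0.1 * sin(2 * pi * 11 * t)
  sse <- vapply(c(1e-5, 1e-3, 1e-1, 0.9999),
                function(p) sum((smooth_series(y, p, time = t) - y)^2),
                numeric(1))
  expect_true(all(diff(sse) < 0))
})

test_that("body-length calibration yields BL units and scale invariance", {
  tr <- toy_track(bl = 200, amp = 25)
  res <- analyze_flight(tr)
  expect_equal(res$A_bl, 50 / 200, tolerance = 5e-3)   # 50 px range / 200 px BL

  # global pixel rescaling leaves every BL-unit quantity unchanged
  tr2 <- toy_track(bl = 200, amp = 25)
  for (lm_ in track_landmarks(tr2)) {
    tr2$data[[paste0(lm_, "_x")]] <- tr2$data[[paste0(lm_, "_x")]] * 3.7
    tr2$data[[paste0(lm_, "_y")]] <- tr2$data[[paste0(lm_, "_y")]] * 3.7
  }
  res2 <- analyze_flight(tr2)
  expect_equal(res2$A_bl, res$A_bl, tolerance = 1e-10)
  expect_equal(res2$st, res$st, tolerance = 1e-10)

  expect_error(
    calibrate_to_body_lengths(tr, rep(-1, nrow(tr$data))), "strictly positive")
})

test_that("camera-distance drift is absorbed by per-frame calibration", {
  p <- clean_params(scale_drift = 2, head_bob_amp = 0.05, n_wingbeats = 6)
  res <- analyze_flight(generate_flight(p))
  expect_equal(res$A_bl, p$excursion_A / p$body_length, tolerance = 0.005)
  expect_lt(res$A_sd_bl / res$A_bl, 0.02)
})

test_that("metric conversion scales lengths but never the Strouhal number", {
  cfg <- tibble::tibble(species = "x", culmen_length_m = 0.05,
                        culmen_to_body_ratio = 0.125, size_class = "medium",
                        airspeed_low = 13.95, airspeed_high = 18.65)
  expect_equal(species_body_length_m("x", cfg), 0.4)
  expect_equal(body_lengths_to_meters(0.5, "x", cfg), 0.2)
  cfg2 <- cfg; cfg2$culmen_to_body_ratio <- 0.25
  expect_equal(body_lengths_to_meters(0.5, "x", cfg2), 0.1)
  expect_error(body_lengths_to_meters(1, "y", cfg), "not found")

  f <- 2.4; A_bl <- 0.28; U_bls <- 3.8
  bl_m <- species_body_length_m("x", cfg)
  expect_identical(strouhal(f, A_bl, U_bls),
                   strouhal(f, A_bl * bl_m, U_bls * bl_m))
})
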