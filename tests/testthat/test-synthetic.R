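test_that("rigid unperturbed body keeps a constant projected eye-tail length", {
  p <- clean_params(descent_angle = 0)
  tr <- generate_flight(p)
  len <- body_length_series(tr)
  expect_equal(diff(range(len)), 0, tolerance = 1e-9)
  expect_equal(mean(len), p$body_length * p$px_per_m, tolerance = 1e-9)
})

test_that("wrist elevation has one maxima-minima pair per generated wingbeat", {
  tr <- generate_flight(clean_params(wingbeat_freq_f = 2.4, n_wingbeats = 5,
                                     frame_rate = 119.88))
  y <- landmark_xy(tr, "wrist")[, 2]
  s <- sign(diff(y))
  turns <- diff(s[s != 0])
  expect_identical(sum(turns < 0), 5L)   # maxima
  expect_gte(sum(turns > 0), 5L)         # minima (endpoint-dependent)
})

test_that("generator refuses unresolvable or degenerate configurations", {
  expect_error(synthetic_flight_params(wingbeat_freq_f = 8, frame_rate = 12),
               "frame rate too low")
  expect_error(synthetic_flight_params(body_length = 0), "zero-length body")
  expect_error(synthetic_flight_params(descent_angle = 91))
  expect_error(synthetic_flight_params(stroke_plane_beta = 5), "beta")
})

test_that("off-axis projection follows the cosine law", {
  tr <- generate_flight(clean_params())
  same <- project_offaxis(tr, 0)
  expect_equal(same$data, tr$data)

  span <- function(x) diff(range(body_midpoint(x)[, 1]))
  tr20 <- project_offaxis(tr, 20)
  reduction <- 100 * (1 - span(tr20) / span(tr))
  expect_equal(reduction, 100 * (1 - cos(20 * pi / 180)), tolerance = 1e-9)
  expect_equal(reduction, 6.031, tolerance = 1e-3)

  tr60 <- project_offaxis(tr, 60)
  expect_equal(span(tr60) / span(tr), 0.5, tolerance = 1e-12)

  expect_error(project_offaxis(tr, 90), "\\[0, 90\\)")
})

test_that("digitization noise is reproducible, unbiased and well-scaled", {
  tr <- generate_flight(clean_params(n_wingbeats = 25))
  expect_identical(add_digitization_noise(tr, 0)$data, tr$data)

  a <- add_digitization_noise(tr, 2, seed = 42)
  b <- add_digitization_noise(tr, 2, seed = 42)
  expect_identical(a$data, b$data)
  c <- add_digitization_noise(tr, 2, seed = 43)
  expect_false(identical(a$data, c$data))

  offsets <- unlist(a$data[-1] - tr$data[-1])
  expect_gt(length(offsets), 1e4)
  expect_equal(sd(offsets), 2, tolerance = 0.05)
  # adding noise must not disturb the caller's RNG stream
  set.seed(7); r1 <- rnorm(1)
  set.seed(7); invisible(add_digitization_noise(tr, 1, seed = 9)); r2 <- rnorm(1)
  expect_identical(r1, r2)
})

test_that("study datasets have the designed cardinality and labels", {
  design <- default_study_design(flights_per_cell = 2,
                                 species = c("common_murre", "tufted_puffin"))
  tracks <- generate_study_dataset(design, seed = 5, noise_sd = 0)
  expect_length(tracks, 2 * nrow(design))
  expect_setequal(unique(vapply(tracks, function(x) x$species, "")),
                  c("common_murre", "tufted_puffin"))
  expect_true(all(vapply(tracks, function(x) !is.null(x$ground_truth), TRUE)))
  expect_error(generate_study_dataset(default_study_design(2)[0, ]), "empty design")
})

test_that("study generation is deterministic under a fixed seed", {
  d <- default_study_design(1, species = "common_murre")
  t1 <- generate_study_dataset(d, seed = 11)
  t2 <- generate_study_dataset(d, seed = 11)
  expect_identical(lapply(t1, function(x) x$data), lapply(t2, function(x) x$data))
})
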