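#' Default geometry and smoothing parameters
#'
#' Tunables for trajectory classification, self-calibration and smoothing.
#'
#' * `horizontal_max_deg` (10): aquatic trajectories shallower than this are
#'   horizontal aquatic flight.
#' * `descending_min_deg` (20): aquatic trajectories steeper than this are
#'   descending aquatic flight; angles in between are left unclassified and
#'   excluded from analysis.
#' * `p_bodylength` (1e-4): smoothing parameter (see [smooth_series()]) for the
#'   per-frame eye-tail body-length series. At typical clip durations this
#'   flattens wingbeat-synchronised head movement while tracking slow changes
#'   in apparent size (camera distance, refraction).
#' * `p_kinematics` (NULL): smoothing parameter for the calibrated landmark
#'   kinematics. `NULL` selects the roughness penalty automatically so that
#'   the spline's half-power frequency sits at `cutoff_mult` times the
#'   flight's dominant wingbeat frequency, capped at `cutoff_max_frac` times
#'   the frame rate; see [kinematic_lambda()].
#' * `cutoff_mult` (5), `cutoff_max_frac` (0.3): see above.
#' * `center_cutoff_ratio` (1/3): the bird-centre reference path (smoothed
#'   eye-tail midpoint) is low-passed at this fraction of the dominant
#'   wingbeat frequency — low enough to reject wingbeat-synchronised head
#'   movement, high enough to follow slow apparent-size drift.
#'
#' @param ... named overrides of the defaults.
#' @return named list of parameters.
#' @export
geometry_params <- function(...) {
  p <- list(
    horizontal_max_deg = 10,
    descending_min_deg = 20,
    p_bodylength = 1e-4,
    p_kinematics = NULL,
    cutoff_mult = 5,
    cutoff_max_frac = 0.3,
    center_cutoff_ratio = 1 / 3
  )
  utils::modifyList(p, list(...))
}

#' Estimate the descent angle of a flight
#'
#' Angle between the bird's mean path and the horizontal, as the magnitude of
#' the slope angle of the least-squares line fitted to the per-frame eye-tail
#' midpoint trajectory (x regressed on, y against x ... the fit is done on
#' y ~ x with x the along-image horizontal coordinate).
#'
#' @param track a `landmark_track` with eye and tail digitized.
#' @return descent angle in degrees (>= 0).
#' @export
estimate_descent_angle <- function(track) {
  mid <- body_midpoint(track)
  if (nrow(mid) < 2) stop("need at least 2 frames", call. = FALSE)
  dx <- diff(range(mid[, 1]))
  dy <- diff(range(mid[, 2]))
  if (dx^2 + dy^2 < .Machine$double.eps) {
    stop("zero net displacement: no defined path for track ", track$flight_id,
         call. = FALSE)
  }
  # orthogonal least-squares line: principal axis of the midpoint cloud,
  # symmetric in x and y so near-vertical dives are handled too
  v <- eigen(stats::cov(mid[complete.cases(mid), , drop = FALSE]))$vectors[, 1]
  ang <- abs(rad2deg(atan2(v[2], v[1]))) %% 180
  min(ang, 180 - ang)
}

#' Classify a flight by fluid and trajectory
#'
#' Air flights are aerial. Aquatic flights are split into horizontal
#' (trajectory < 10 deg by default) and descending (> 20 deg); trajectories in
#' the 10-20 deg gap belong to neither defined class and come back
#' `"unclassified"`, to be excluded from analysis.
#'
#' @param descent_angle degrees, >= 0.
#' @param fluid `"air"` or `"water"`.
#' @param params see [geometry_params()].
#' @return one of `"aerial"`, `"horizontal_aquatic"`, `"descending_aquatic"`,
#'   `"unclassified"`.
#' @export
classify_flight <- function(descent_angle, fluid = c("water", "air"),
                            params = geometry_params()) {
  fluid <- match.arg(fluid)
  stopifnot(is.finite(descent_angle), descent_angle >= 0)
  if (fluid == "air") return("aerial")
  if (descent_angle < params$horizontal_max_deg) return("horizontal_aquatic")
  if (descent_angle > params$descending_min_deg) return("descending_aquatic")
  "unclassified"
}

#' Rotate a track into the path-aligned frame
#'
#' Rigid 2-D rotation of every landmark about the track centroid so that the
#' descending travel direction becomes +x and the perpendicular (dorsoventral)
#' direction +y. Coordinates are y-up with depth increase mapping to -y, so a
#' positive descent angle rotates points counter-clockwise, bringing the
#' down-sloping path level. Inter-landmark distances are preserved exactly;
#' only descending aquatic tracks are rotated in the pipeline (horizontal and
#' aerial tracks pass through unchanged, their axes being already aligned
#' with travel).
#'
#' @param track a `landmark_track`.
#' @param descent_angle degrees.
#' @return the rotated track.
#' @export
rotate_to_path_frame <- function(track, descent_angle) {
  stopifnot(is.finite(descent_angle))
  lms <- track_landmarks(track)
  all_xy <- do.call(rbind, lapply(lms, landmark_xy, track = track))
  ctr <- colMeans(all_xy[complete.cases(all_xy), , drop = FALSE])
  for (lm_ in lms) {
    xy <- landmark_xy(track, lm_)
    rot <- rotate_points(sweep(xy, 2, ctr), descent_angle)
    track <- set_landmark_xy(track, lm_, sweep(rot, 2, ctr, FUN = "+"))
  }
  track
}

#' Per-frame body length of a bird
#'
#' Euclidean distance between the eye and the distal tip of the tail in each
#' frame, in pixels. This series carries both the true (head-movement) and the
#' apparent (camera distance, refraction) variation in body length; smoothed,
#' it is the self-calibration scale.
#'
#' @param track a `landmark_track` with eye and tail.
#' @return numeric vector, one value per frame.
#' @export
body_length_series <- function(track) {
  d <- landmark_xy(track, "eye") - landmark_xy(track, "tail")
  len <- sqrt(rowSums(d^2))
  if (any(len < .Machine$double.eps, na.rm = TRUE)) {
    stop("coincident eye and tail in at least one frame", call. = FALSE)
  }
  len
}

# Map the package smoothing conventions onto stats::smooth.spline's lambda.
# smooth.spline penalises on x scaled to [0, 1]; a roughness weight
# lambda_sec expressed with time in seconds therefore becomes
# lambda_sec / range(time)^3 on the scaled abscissa.
smooth_lambda_scaled <- function(time, lambda_sec) {
  r <- diff(range(time))
  max(lambda_sec / r^3, 1e-12)
}

# Fit a penalised cubic smoothing spline, returning an evaluator closure.
# Exactly one of p (fidelity weight, criterion p*SSE + (1-p)*integral of
# squared curvature, time in seconds) or lambda_sec (the equivalent raw
# roughness weight (1-p)/p) must be given.
fit_smoother <- function(time, y, p = NULL, lambda_sec = NULL) {
  ok <- is.finite(y) & is.finite(time)
  if (sum(ok) < 4) stop("need at least 4 finite points to smooth", call. = FALSE)
  if (is.null(lambda_sec)) {
    if (is.null(p) || !is.numeric(p) || p <= 0 || p > 1) {
      stop("smoothing parameter must lie in (0, 1]", call. = FALSE)
    }
    lambda_sec <- (1 - p) / p
  }
  fit <- smooth.spline(time[ok], y[ok],
                       lambda = smooth_lambda_scaled(time[ok], lambda_sec),
                       all.knots = TRUE, keep.data = FALSE, cv = FALSE)
  structure(
    list(
      fit = fit,
      lambda_sec = lambda_sec,
      predict = function(t, deriv = 0) predict(fit, t, deriv = deriv)$y
    ),
    class = "ak_smoother"
  )
}

#' Smooth a time series with a penalised cubic spline
#'
#' Fits a cubic smoothing spline minimising
#' `p * sum((y - f)^2) + (1 - p) * integral(f''(t)^2 dt)` with the abscissa in
#' seconds, and evaluates it at the input times. `p` near 1 reproduces the
#' data; `p` near 0 tends to the least-squares line. Constants and straight
#' lines are reproduced exactly for every `p` (their curvature penalty is
#' zero). The numeric value of a smoothing parameter is convention-dependent:
#' values quoted for other toolboxes (whose penalties are scaled by knot
#' spacing) are only approximately comparable to `p` here.
#'
#' @param series numeric vector.
#' @param p smoothing parameter in `(0, 1]`.
#' @param time abscissa in seconds; defaults to an index grid at `frame_rate`.
#' @param frame_rate used to build `time` when not supplied.
#' @return smoothed series, same length as the input.
#' @export
smooth_series <- function(series, p, time = NULL, frame_rate = 1) {
  if (is.null(time)) time <- (seq_along(series) - 1) / frame_rate
  sm <- fit_smoother(time, series, p = p)
  sm$predict(time)
}

#' Automatic roughness weight for kinematic smoothing
#'
#' Chooses the roughness weight of the kinematic smoothing stage from its
#' intended effect: treating the spline as the low-pass filter
#' `H(omega) = 1 / (1 + lambda * h * omega^4)` (h = sampling interval), the
#' weight is set so the half-power point sits at `cutoff_mult` times the
#' flight's dominant wingbeat frequency, capped at `cutoff_max_frac` times the
#' frame rate. This suppresses frame-level digitization jitter while
#' attenuating the wingbeat signal itself by well under 1 percent.
#'
#' @param frame_rate frames per second.
#' @param dominant_freq dominant oscillation frequency of the series, Hz.
#' @param params see [geometry_params()].
#' @return `lambda_sec`, the raw roughness weight in the package's
#'   seconds-based convention.
#' @export
kinematic_lambda <- function(frame_rate, dominant_freq, params = geometry_params()) {
  f_c <- min(params$cutoff_mult * dominant_freq,
             params$cutoff_max_frac * frame_rate)
  h <- 1 / frame_rate
  1 / (h * (2 * pi * f_c)^4)
}

# Dominant oscillation frequency from mean crossings of a series.
dominant_frequency <- function(series, time) {
  x <- series - mean(series, na.rm = TRUE)
  s <- sign(x)
  s[s == 0] <- 1
  crossings <- which(diff(s) != 0)
  if (length(crossings) < 2) {
    stop("no oscillation detected: cannot estimate dominant frequency",
         call. = FALSE)
  }
  # successive mean crossings are half periods apart
  mean_half <- (time[crossings[length(crossings)]] - time[crossings[1]]) /
    (length(crossings) - 1)
  1 / (2 * mean_half)
}

#' Calibrate a track to body-length units
#'
#' Divides each frame's coordinates by that frame's smoothed body length,
#' converting pixels to body lengths (BL). Because the scale is per-frame, the
#' calibration absorbs variability in camera-to-bird distance and refraction
#' along the flight. The result is a `path_frame_track`: the input track with
#' calibrated coordinates plus the calibration series and classification
#' attached.
#'
#' @param track a `landmark_track`, already rotated if descending.
#' @param smoothed_body_length strictly positive per-frame series (pixels).
#' @param descent_angle degrees (stored).
#' @param flight_class stored classification label.
#' @return a `path_frame_track` (subclass of `landmark_track`).
#' @export
calibrate_to_body_lengths <- function(track, smoothed_body_length,
                                      descent_angle = 0,
                                      flight_class = "unclassified") {
  if (any(!is.finite(smoothed_body_length)) || any(smoothed_body_length <= 0)) {
    stop("smoothed body length must be strictly positive", call. = FALSE)
  }
  if (length(smoothed_body_length) != nrow(track$data)) {
    stop("calibration series length must match the number of frames", call. = FALSE)
  }
  for (lm_ in track_landmarks(track)) {
    track <- set_landmark_xy(track, lm_,
                             landmark_xy(track, lm_) / smoothed_body_length)
  }
  track$smoothed_body_length <- smoothed_body_length
  track$descent_angle <- descent_angle
  track$flight_class <- flight_class
  class(track) <- c("path_frame_track", class(track))
  track
}

#' Convert body lengths to meters for one species
#'
#' Body length is inferred from the culmen: `body_length_m = culmen_length /
#' culmen_to_body_ratio`, both taken from the species configuration. Only
#' metric reporting is affected; the Strouhal number is dimensionless and
#' identical in either unit system.
#'
#' @param value_bl value in body lengths.
#' @param species species label, present in `species_config`.
#' @param species_config table from [load_species_config()].
#' @return value in meters.
#' @export
body_lengths_to_meters <- function(value_bl, species, species_config) {
  row <- species_config[species_config$species == species, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("species '", species, "' not found in species config", call. = FALSE)
  }
  value_bl * row$culmen_length_m / row$culmen_to_body_ratio
}

#' Species body length in meters
#' @inheritParams body_lengths_to_meters
#' @return scalar body length (m).
#' @export
species_body_length_m <- function(species, species_config) {
  body_lengths_to_meters(1, species, species_config)
}
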