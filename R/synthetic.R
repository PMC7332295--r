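#' Parameters of a synthetic flight
#'
#' Ground-truth description of a "virtual alcid" used by [generate_flight()].
#' The motion model is a body reference point translating at `speed_U` along a
#' straight path `descent_angle` degrees below horizontal, with (i) sinusoidal
#' wrist elevation of peak-to-trough `excursion_A` at `wingbeat_freq_f`,
#' directed along a stroke plane at `stroke_plane_beta` to the travel
#' direction, (ii) head movement along the body axis in sync with the
#' wingbeat, (iii) sinusoidal body pitching about the eye-tail midpoint, and
#' (iv) a wingtip placed so the wingtip-to-wrist chord makes
#' `chord_alpha_up` / `chord_alpha_down` degrees with the tail-to-eye axis at
#' mid-upstroke / mid-downstroke, blended sinusoidally in between.
#'
#' Camera effects applied afterwards: off-axis foreshortening of along-path
#' coordinates (`camera_offaxis`), a pixel scale with optional linear
#' apparent-size drift (`scale_drift`, emulating a change in camera-to-bird
#' distance), and i.i.d. Gaussian digitization noise (`noise_sd` pixels). The
#' default `noise_sd` is calibrated so that the apparent eye-tail body-length
#' jitter is about 1 percent of body length.
#'
#' @param species_label species name carried into metadata.
#' @param fluid `"water"` or `"air"`.
#' @param view `"perpendicular"` (eye/tail/shoulder/wrist/wingtip) or
#'   `"parallel"` (shoulder/wrist seen head-on; `amplitude_deg` drives the
#'   angular wing sweep).
#' @param body_length eye-to-tail length (m).
#' @param speed_U speed along the path (m/s, >= 0).
#' @param descent_angle degrees below horizontal, in `[0, 90]`.
#' @param wingbeat_freq_f wingbeat frequency (Hz).
#' @param excursion_A peak-to-trough wrist elevation (m).
#' @param stroke_plane_beta stroke-plane angle (deg, in (15, 165)): angle
#'   between forward travel and the downstroke displacement vector; < 90 means
#'   the downstroke sweeps down-and-forward.
#' @param chord_alpha_up,chord_alpha_down chord angles at mid-half-stroke (deg).
#' @param amplitude_deg angular wing sweep for parallel-view flights (deg).
#' @param head_bob_amp head-movement amplitude, fraction of body length.
#' @param pitch_amp body pitch amplitude (deg).
#' @param camera_offaxis angle between path and image plane (deg, `[0, 90)`).
#' @param noise_sd digitization noise (pixels); `NULL` = 1 percent body-length
#'   jitter default.
#' @param frame_rate camera rate (fps); must exceed `2 * wingbeat_freq_f`.
#' @param n_wingbeats number of wingbeat cycles generated.
#' @param seed integer seed for the digitization noise.
#' @param px_per_m pixel scale of the camera.
#' @param origin_px image offset (pixels) added after scaling.
#' @param scale_drift apparent-size multiplier reached at the last frame
#'   (linear in time; 1 = no drift).
#' @param phase0,pitch_phase,bob_phase phase offsets (radians).
#' @param shoulder_offset wrist-base position along the body axis from the
#'   midpoint, fraction of body length.
#' @param chord_fraction wingtip-to-wrist chord length, fraction of body length.
#' @param wing_fraction shoulder-to-wrist radius (parallel view), fraction of
#'   body length.
#' @return validated list of class `synthetic_flight_params`.
#' @export
synthetic_flight_params <- function(species_label = "common_murre",
                                    fluid = c("water", "air"),
                                    view = c("perpendicular", "parallel"),
                                    body_length = 0.43,
                                    speed_U = 1.63,
                                    descent_angle = 0,
                                    wingbeat_freq_f = 2.4,
                                    excursion_A = 0.122,
                                    stroke_plane_beta = 92,
                                    chord_alpha_up = 40,
                                    chord_alpha_down = 50,
                                    amplitude_deg = 80,
                                    head_bob_amp = 0,
                                    pitch_amp = 0,
                                    camera_offaxis = 0,
                                    noise_sd = NULL,
                                    frame_rate = 119.88,
                                    n_wingbeats = 5,
                                    seed = 1L,
                                    px_per_m = 1000,
                                    origin_px = c(100, 400),
                                    scale_drift = 1,
                                    phase0 = 0,
                                    pitch_phase = 0,
                                    bob_phase = pi / 3,
                                    shoulder_offset = 0.1,
                                    chord_fraction = 0.25,
                                    wing_fraction = 0.35) {
  p <- list(
    species_label = species_label, fluid = match.arg(fluid),
    view = match.arg(view), body_length = body_length, speed_U = speed_U,
    descent_angle = descent_angle, wingbeat_freq_f = wingbeat_freq_f,
    excursion_A = excursion_A, stroke_plane_beta = stroke_plane_beta,
    chord_alpha_up = chord_alpha_up, chord_alpha_down = chord_alpha_down,
    amplitude_deg = amplitude_deg, head_bob_amp = head_bob_amp,
    pitch_amp = pitch_amp, camera_offaxis = camera_offaxis,
    noise_sd = noise_sd, frame_rate = frame_rate, n_wingbeats = n_wingbeats,
    seed = seed, px_per_m = px_per_m, origin_px = origin_px,
    scale_drift = scale_drift, phase0 = phase0, pitch_phase = pitch_phase,
    bob_phase = bob_phase, shoulder_offset = shoulder_offset,
    chord_fraction = chord_fraction, wing_fraction = wing_fraction
  )
  if (is.null(p$noise_sd)) {
    p$noise_sd <- 0.01 * body_length * px_per_m / sqrt(2)
  }
  class(p) <- "synthetic_flight_params"
  validate_synthetic_flight_params(p)
}

validate_synthetic_flight_params <- function(p) {
  if (!is.numeric(p$body_length) || p$body_length <= 0) {
    stop("body_length must be > 0 (zero-length body)", call. = FALSE)
  }
  stopifnot(
    p$speed_U >= 0,
    p$wingbeat_freq_f > 0,
    p$excursion_A > 0,
    p$descent_angle >= 0, p$descent_angle <= 90,
    p$noise_sd >= 0,
    p$camera_offaxis >= 0, p$camera_offaxis < 90,
    p$n_wingbeats >= 1,
    p$scale_drift > 0
  )
  if (p$frame_rate <= 2 * p$wingbeat_freq_f) {
    stop("frame rate too low to resolve wingbeat extrema (need > 2f)",
         call. = FALSE)
  }
  if (p$view == "perpendicular" &&
      (p$stroke_plane_beta <= 15 || p$stroke_plane_beta >= 165)) {
    stop("stroke_plane_beta must lie in (15, 165) degrees", call. = FALSE)
  }
  invisible(p)
}

#' Generate a synthetic landmark track
#'
#' Forward-simulates the motion model of [synthetic_flight_params()], projects
#' it to pixels (off-axis foreshortening, pixel scale with optional
#' apparent-size drift) and adds digitization noise. The generating parameters
#' travel with the track as `$ground_truth`, so estimators can be checked by
#' parameter recovery; the estimators themselves never read it.
#'
#' @param params a `synthetic_flight_params` object.
#' @param flight_id identifier for the track.
#' @return a `landmark_track`.
#' @export
generate_flight <- function(params = synthetic_flight_params(),
                            flight_id = "synthetic") {
  p <- validate_synthetic_flight_params(params)
  fps <- p$frame_rate
  f <- p$wingbeat_freq_f
  L <- p$body_length
  duration <- p$n_wingbeats / f
  frame <- 0:floor(duration * fps)
  t <- frame / fps
  omega <- 2 * pi * f

  if (p$view == "perpendicular") {
    psi <- deg2rad(p$pitch_amp) * sin(omega * t + p$pitch_phase)
    b <- cbind(cos(psi), sin(psi))                     # cranial unit vector
    mid <- cbind(p$speed_U * t, 0)
    bob <- p$head_bob_amp * L * sin(omega * t + p$bob_phase)
    eye <- mid + (L / 2 + bob) * b
    tail_ <- mid - (L / 2) * b
    shoulder <- mid + p$shoulder_offset * L * b
    s <- (p$excursion_A / 2) * sin(omega * t + p$phase0)
    beta <- deg2rad(p$stroke_plane_beta)
    # elevation equals s(t); the stroke path makes beta with the travel axis
    wrist <- shoulder + cbind(-s / tan(beta), s)
    alpha <- deg2rad((p$chord_alpha_up + p$chord_alpha_down) / 2 +
                       (p$chord_alpha_up - p$chord_alpha_down) / 2 *
                       cos(omega * t + p$phase0))
    # chord direction: body axis rotated clockwise by alpha
    chord <- cbind(b[, 1] * cos(alpha) + b[, 2] * sin(alpha),
                   -b[, 1] * sin(alpha) + b[, 2] * cos(alpha))
    wingtip <- wrist - p$chord_fraction * L * chord
    pts <- list(eye = eye, tail = tail_, shoulder = shoulder,
                wrist = wrist, wingtip = wingtip)
    # embed the path frame in the world: travel descends at descent_angle,
    # depth increase maps to -y
    if (p$descent_angle != 0) {
      pts <- lapply(pts, rotate_points, angle_deg = -p$descent_angle)
    }
  } else {
    gamma <- deg2rad(p$amplitude_deg / 2) * sin(omega * t + p$phase0)
    shoulder <- cbind(rep(0, length(t)), rep(0, length(t)))
    wrist <- shoulder + p$wing_fraction * L * cbind(cos(gamma), sin(gamma))
    pts <- list(shoulder = shoulder, wrist = wrist)
  }

  # camera: off-axis foreshortening of the horizontal coordinates, then pixel
  # scale with linear apparent-size drift about the image origin
  if (p$camera_offaxis > 0) {
    pts <- lapply(pts, function(m) {
      m[, 1] <- m[, 1] * cos(deg2rad(p$camera_offaxis)); m
    })
  }
  k <- 1 + (p$scale_drift - 1) * (t - t[1]) / max(t[length(t)] - t[1], 1e-12)
  pts <- lapply(pts, function(m) {
    cbind(p$origin_px[1] + k * p$px_per_m * m[, 1],
          p$origin_px[2] + k * p$px_per_m * m[, 2])
  })

  d <- tibble::tibble(frame = frame)
  for (nm in names(pts)) {
    d[[paste0(nm, "_x")]] <- pts[[nm]][, 1]
    d[[paste0(nm, "_y")]] <- pts[[nm]][, 2]
  }
  gt <- unclass(p)
  gt$excursion_A_bl <- p$excursion_A / L
  gt$speed_U_bls <- p$speed_U / L
  gt$st_true <- if (p$speed_U > 0) f * p$excursion_A / p$speed_U else NA_real_
  track <- landmark_track(d, frame_rate = fps, species = p$species_label,
                          fluid = p$fluid, view = p$view,
                          flight_id = flight_id, ground_truth = gt)
  if (p$noise_sd > 0) {
    track <- add_digitization_noise(track, p$noise_sd, seed = p$seed)
  }
  track
}

#' Foreshorten a track filmed off-perpendicular
#'
#' A flight path rotated `camera_offaxis` degrees out of the image plane has
#' its along-path horizontal displacements compressed by the cosine law:
#' horizontal (x) coordinates are scaled by `cos(camera_offaxis)`; vertical
#' coordinates are unchanged. At 20 degrees the compression is about 6
#' percent.
#'
#' @param track a `landmark_track`.
#' @param camera_offaxis degrees, in `[0, 90)`.
#' @return the foreshortened track.
#' @export
project_offaxis <- function(track, camera_offaxis) {
  if (!is.numeric(camera_offaxis) || camera_offaxis < 0 || camera_offaxis >= 90) {
    stop("camera_offaxis must lie in [0, 90) degrees", call. = FALSE)
  }
  if (camera_offaxis == 0) return(track)
  co <- cos(deg2rad(camera_offaxis))
  for (lm_ in track_landmarks(track)) {
    xy <- landmark_xy(track, lm_)
    xy[, 1] <- xy[, 1] * co
    track <- set_landmark_xy(track, lm_, xy)
  }
  track
}

#' Add Gaussian digitization noise to a track
#'
#' Adds i.i.d. Gaussian offsets independently per landmark, frame and axis,
#' emulating manual digitization error. Reproducible under a fixed seed; the
#' global RNG state is left untouched.
#'
#' @param track a `landmark_track`.
#' @param noise_sd standard deviation in pixels (>= 0).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return the noisy track.
#' @export
add_digitization_noise <- function(track, noise_sd, seed = NULL) {
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  if (noise_sd == 0) return(track)
  with_seed(seed, {
    for (lm_ in track_landmarks(track)) {
      xy <- landmark_xy(track, lm_)
      xy <- xy + matrix(rnorm(length(xy), 0, noise_sd), ncol = 2)
      track <- set_landmark_xy(track, lm_, xy)
    }
    track
  })
}
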