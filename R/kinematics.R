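#' Analysis parameters
#'
#' Extends [geometry_params()] with the wingbeat-kinematics tunables:
#'
#' * `prominence_fraction` (0.10): elevation extrema whose local
#'   peak-to-trough range falls below this fraction of the flight's median
#'   range are treated as jitter, not half-strokes.
#' * `stroke_velocity_mode` (`"per_stroke"`): `"per_stroke"` divides each
#'   half-stroke's angular sweep by its own duration; `"approx"` uses
#'   `0.5 / f` as the stroke duration (the usable choice at low frame rates).
#' * `pitch_correction` (TRUE): subtract the pitch-induced component of tail
#'   velocity before averaging translational velocity.
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
analysis_params <- function(...) {
  p <- c(geometry_params(), list(
    prominence_fraction = 0.10,
    stroke_velocity_mode = "per_stroke",
    pitch_correction = TRUE
  ))
  utils::modifyList(p, list(...))
}

# ---- smoothed-track machinery -----------------------------------------------

# Wing landmark used for elevation, by fluid (wrist in water, wingtip in air),
# falling back to whichever is present.
wing_landmark <- function(track) {
  present <- track_landmarks(track)
  if (track$view == "parallel") return("wrist")
  pref <- if (track$fluid == "water") c("wrist", "wingtip") else c("wingtip", "wrist")
  pref[pref %in% present][1]
}

#' Smooth all landmark coordinates of a track
#'
#' Second smoothing stage: fits a penalised cubic spline to every coordinate
#' series to suppress digitization error of the landmarks themselves. The
#' roughness weight comes from `params$p_kinematics` if set, otherwise from
#' [kinematic_lambda()] driven by the dominant frequency of the wing
#' elevation signal. The spline fits are kept on the track (`$smoothers`) so
#' downstream estimators can evaluate positions, sub-frame refinements and
#' derivatives continuously.
#'
#' @param track a calibrated `path_frame_track` (or a parallel-view
#'   `landmark_track`).
#' @param params see [analysis_params()].
#' @return the track with smoothed coordinates and attached smoothers.
#' @export
smooth_track <- function(track, params = analysis_params()) {
  t <- track_time(track)
  wl <- wing_landmark(track)
  elev_raw <- if (track$view == "parallel") {
    landmark_xy(track, "wrist")[, 2] - landmark_xy(track, "shoulder")[, 2]
  } else {
    landmark_xy(track, wl)[, 2] - body_midpoint(track)[, 2]
  }
  f0 <- tryCatch(dominant_frequency(elev_raw, t), error = function(e) NULL)
  if (!is.null(params$p_kinematics)) {
    lambda <- (1 - params$p_kinematics) / params$p_kinematics
  } else {
    if (is.null(f0)) stop("no oscillation detected in wing elevation", call. = FALSE)
    lambda <- kinematic_lambda(track$frame_rate, f0, params)
  }
  fits <- list()
  for (lm_ in track_landmarks(track)) {
    xy <- landmark_xy(track, lm_)
    fx <- fit_smoother(t, xy[, 1], lambda_sec = lambda)
    fy <- fit_smoother(t, xy[, 2], lambda_sec = lambda)
    fits[[lm_]] <- list(x = fx, y = fy)
    track <- set_landmark_xy(track, lm_, cbind(fx$predict(t), fy$predict(t)))
  }
  track$smoothers <- fits
  track$kin_lambda <- lambda
  # bird-centre reference: the eye-tail midpoint path, low-passed below the
  # wingbeat so head movement cannot leak into bird-centred vectors while
  # slow apparent-size drift is still followed
  if (all(c("eye", "tail") %in% track_landmarks(track))) {
    mid <- body_midpoint(track)
    lam_ctr <- if (!is.null(f0)) {
      f_ctr <- params$center_cutoff_ratio * f0
      1 / ((1 / track$frame_rate) * (2 * pi * f_ctr)^4)
    } else {
      (1 - params$p_bodylength) / params$p_bodylength
    }
    track$center_smoother <- list(
      x = fit_smoother(t, mid[, 1], lambda_sec = lam_ctr),
      y = fit_smoother(t, mid[, 2], lambda_sec = lam_ctr)
    )
  }
  track
}

# Evaluate a smoothed landmark (matrix n x 2) at arbitrary times.
sm_xy <- function(strack, landmark, t, deriv = 0) {
  f <- strack$smoothers[[landmark]]
  if (is.null(f)) stop("track has no smoother for ", landmark, call. = FALSE)
  cbind(f$x$predict(t, deriv = deriv), f$y$predict(t, deriv = deriv))
}

# Bird-centred position of a landmark: landmark minus the (strongly
# smoothed) eye-tail midpoint path.
sm_centered <- function(strack, landmark, t) {
  ctr <- if (!is.null(strack$center_smoother)) {
    cbind(strack$center_smoother$x$predict(t), strack$center_smoother$y$predict(t))
  } else {
    (sm_xy(strack, "eye", t) + sm_xy(strack, "tail", t)) / 2
  }
  sm_xy(strack, landmark, t) - ctr
}

# ---- segmentation ------------------------------------------------------------

#' Segment wingbeats from an elevation series
#'
#' Finds alternating minima and maxima of a (smoothed) wing elevation series,
#' discards extrema whose local range is below `prominence_fraction` of the
#' flight's median peak-to-trough range, refines each surviving extremum to
#' sub-frame precision on an interpolating cubic spline, and returns the
#' complete half-strokes between consecutive extrema. Leading and trailing
#' incomplete half-strokes fall away by construction.
#'
#' @param elevation_series numeric vector (already smoothed).
#' @param frame_rate frames per second.
#' @param prominence_fraction see [analysis_params()].
#' @param time optional abscissa (seconds).
#' @return tibble of half-strokes: `half_stroke` (`"upstroke"` from minimum to
#'   maximum, `"downstroke"` from maximum to minimum), start/end times and
#'   elevations, `idx_min` / `idx_max` (0-based frames of the bounding
#'   extrema), `elevation_min` / `elevation_max`, `duration`, `mid_time` and
#'   `mid_frame`. The refined extrema sequence is attached as
#'   `attr(, "extrema")`.
#' @export
segment_wingbeats <- function(elevation_series, frame_rate,
                              prominence_fraction = 0.10, time = NULL) {
  y <- as.numeric(elevation_series)
  n <- length(y)
  if (is.null(time)) time <- (seq_len(n) - 1) / frame_rate
  if (n < 5) stop("no wingbeats detected: series too short", call. = FALSE)

  dy <- diff(y)
  sgn <- sign(dy)
  sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1L          # interior extremum indices
  if (length(turns) < 2) {
    stop("no wingbeats detected: fewer than two elevation extrema", call. = FALSE)
  }
  type <- ifelse(sgn[turns - 1] > 0, "max", "min")

  # collapse consecutive same-type extrema to the most extreme one
  collapse <- function(idx, typ) {
    keep <- rep(TRUE, length(idx))
    i <- 1
    while (i < length(idx)) {
      j <- i + 1
      while (j <= length(idx) && typ[j] == typ[i]) j <- j + 1
      if (j - i > 1) {
        grp <- i:(j - 1)
        best <- if (typ[i] == "max") grp[which.max(y[idx[grp]])] else grp[which.min(y[idx[grp]])]
        keep[setdiff(grp, best)] <- FALSE
      }
      i <- j
    }
    list(idx = idx[keep], typ = typ[keep])
  }
  ex <- collapse(turns, type)

  # prominence pruning: repeatedly delete the weakest adjacent extremum pair
  repeat {
    if (length(ex$idx) < 2) {
      stop("no wingbeats detected after prominence filtering", call. = FALSE)
    }
    rng <- abs(diff(y[ex$idx]))
    thr <- prominence_fraction * median(rng)
    w <- which.min(rng)
    if (rng[w] >= thr) break
    drop <- c(w, w + 1)
    ex <- collapse(ex$idx[-drop], ex$typ[-drop])
  }

  # sub-frame refinement on an interpolating spline
  sf <- splinefun(time, y, method = "fmm")
  h <- median(diff(time))
  refine <- function(i0, typ) {
    tg <- seq(max(time[1], time[i0] - 1.5 * h),
              min(time[n], time[i0] + 1.5 * h), length.out = 61)
    yg <- sf(tg)
    k <- if (typ == "max") which.max(yg) else which.min(yg)
    c(t = tg[k], e = yg[k])
  }
  ref <- t(mapply(refine, ex$idx, ex$typ))
  extrema <- tibble::tibble(
    type = ex$typ, frame_idx = ex$idx - 1L,
    t = ref[, "t"], elevation = ref[, "e"]
  )

  k <- nrow(extrema)
  seg <- tibble::tibble(
    half_stroke = ifelse(extrema$type[-k] == "min", "upstroke", "downstroke"),
    t_start = extrema$t[-k], t_end = extrema$t[-1],
    e_start = extrema$elevation[-k], e_end = extrema$elevation[-1],
    idx_min = ifelse(extrema$type[-k] == "min", extrema$frame_idx[-k],
                     extrema$frame_idx[-1]),
    idx_max = ifelse(extrema$type[-k] == "max", extrema$frame_idx[-k],
                     extrema$frame_idx[-1])
  )
  seg$elevation_min <- pmin(seg$e_start, seg$e_end)
  seg$elevation_max <- pmax(seg$e_start, seg$e_end)
  seg$duration <- seg$t_end - seg$t_start
  seg$mid_time <- (seg$t_start + seg$t_end) / 2
  seg$mid_frame <- round(seg$mid_time * frame_rate)
  if (any(seg$duration <= 0) || any(seg$elevation_max <= seg$elevation_min)) {
    stop("degenerate half-stroke detected", call. = FALSE)
  }
  attr(seg, "extrema") <- extrema
  attr(seg, "frame_rate") <- frame_rate
  seg
}

# Times of refined elevation minima (wingbeat boundaries).
minima_times <- function(segments) {
  ex <- attr(segments, "extrema")
  ex$t[ex$type == "min"]
}

#' Per-wingbeat wing excursion
#'
#' The difference between the maximum and minimum wing elevation within each
#' wingbeat (one value per upstroke segment), in the units of the elevation
#' series (body lengths after calibration). Elevation is measured
#' perpendicular to travel, relative to the eye-tail average.
#'
#' @param segments from [segment_wingbeats()].
#' @return numeric vector of excursions, one per complete half-stroke pair.
#' @export
wing_excursion <- function(segments) {
  up <- segments[segments$half_stroke == "upstroke", , drop = FALSE]
  if (nrow(up) == 0) stop("no complete wingbeats", call. = FALSE)
  up$elevation_max - up$elevation_min
}

#' Wingbeat frequency
#'
#' `mode = "per_wingbeat"`: the inverse of each wingbeat's duration (time
#' between successive elevation minima), one value per wingbeat — the aquatic
#' convention. `mode = "per_flight"`: the number of complete wingbeats
#' divided by their total duration — the aerial convention, robust at low
#' frame rates.
#'
#' @param segments from [segment_wingbeats()].
#' @param mode `"per_wingbeat"` or `"per_flight"`.
#' @return numeric vector (per wingbeat) or scalar (per flight), Hz.
#' @export
wingbeat_frequency <- function(segments, mode = c("per_wingbeat", "per_flight")) {
  mode <- match.arg(mode)
  tm <- minima_times(segments)
  if (length(tm) < 2) stop("zero complete wingbeats", call. = FALSE)
  durations <- diff(tm)
  if (mode == "per_wingbeat") 1 / durations
  else (length(tm) - 1) / (tm[length(tm)] - tm[1])
}

#' Stroke-plane angle of each downstroke
#'
#' The angle between the forward travel direction (+x in the path frame) and
#' the bird-centred displacement of the wing landmark from its elevation
#' maximum to the following minimum, in `[0, 180]` degrees. Values below 90
#' mean the downstroke sweeps down-and-forward (top of the stroke plane
#' rotated caudally), as in aerial flight; values above 90 mean
#' down-and-backward, as in aquatic flight.
#'
#' @param strack a smoothed, calibrated track (see [smooth_track()]).
#' @param segments from [segment_wingbeats()].
#' @param landmark wing landmark; default per fluid (wrist in water, wingtip
#'   in air).
#' @return numeric vector, one angle per downstroke.
#' @export
stroke_plane_angle <- function(strack, segments, landmark = wing_landmark(strack)) {
  dn <- segments[segments$half_stroke == "downstroke", , drop = FALSE]
  if (nrow(dn) == 0) stop("no downstrokes in segments", call. = FALSE)
  p_max <- sm_centered(strack, landmark, dn$t_start)
  p_min <- sm_centered(strack, landmark, dn$t_end)
  disp <- p_min - p_max
  len <- sqrt(rowSums(disp^2))
  if (any(len < 1e-12)) {
    stop("stroke extrema coincide in space", call. = FALSE)
  }
  rad2deg(acos(pmin(1, pmax(-1, disp[, 1] / len))))
}

#' Chord angle at mid-half-stroke
#'
#' The angle between the wingtip-to-wrist vector and the tail-to-eye body
#' axis, evaluated at the temporal midpoint of each half-stroke, in
#' `[0, 180]` degrees (0 = chord parallel to the body axis pointing
#' cranially). Requires both wrist and wingtip; measured for aquatic
#' perpendicular flights.
#'
#' @param strack a smoothed, calibrated track.
#' @param segments from [segment_wingbeats()].
#' @return tibble with `half_stroke`, `mid_time`, `alpha_deg`.
#' @export
chord_angle <- function(strack, segments) {
  present <- track_landmarks(strack)
  if (!all(c("wrist", "wingtip") %in% present)) {
    stop("chord angle needs both wrist and wingtip digitized", call. = FALSE)
  }
  tm <- segments$mid_time
  chord <- sm_xy(strack, "wrist", tm) - sm_xy(strack, "wingtip", tm)
  axis <- sm_xy(strack, "eye", tm) - sm_xy(strack, "tail", tm)
  alpha <- vapply(seq_len(nrow(segments)), function(i) {
    angle_between(chord[i, ], axis[i, ])
  }, numeric(1))
  tibble::tibble(half_stroke = segments$half_stroke, mid_time = tm,
                 alpha_deg = alpha)
}

#' Wingbeat amplitude from shoulder and wrist positions
#'
#' Angle subtended at the shoulder between the shoulder-to-wrist vectors at
#' the elevation maximum and minimum of a wingbeat, in degrees. Parallel-view
#' measurement.
#'
#' @param shoulder length-2 shoulder position (or n x 2 matrix).
#' @param wrist_at_max,wrist_at_min wrist positions at the elevation extrema.
#' @return amplitude in degrees.
#' @export
wingbeat_amplitude_deg <- function(shoulder, wrist_at_max, wrist_at_min) {
  angle_between(wrist_at_max - shoulder, wrist_at_min - shoulder)
}

#' Stroke velocity
#'
#' Angular sweep of a half-stroke divided by its duration, in deg/s. With
#' `mode = "approx"` callers should pass `0.5 / f` as the duration: at frame
#' rates too low to time individual strokes, half the wingbeat period stands
#' in for the stroke duration.
#'
#' @param amplitude_deg angular sweep (deg).
#' @param stroke_duration_s duration (s, > 0).
#' @return deg/s.
#' @export
stroke_velocity <- function(amplitude_deg, stroke_duration_s) {
  if (any(stroke_duration_s <= 0)) stop("stroke duration must be > 0", call. = FALSE)
  amplitude_deg / stroke_duration_s
}

#' Pitch-corrected translational velocity
#'
#' Along-path speed of the bird in body lengths per second. For aquatic
#' flights the tail drives the estimate (the head is an unreliable proxy for
#' body motion); body pitching rotates the tail about the eye-tail midpoint,
#' so the pitch-induced component `dphi/dt x r` (with `r` the
#' midpoint-to-tail vector and `phi` the body pitch from the tail-to-eye
#' vector) is subtracted vectorially before taking the along-path component.
#' For aerial flights the eye-tail midpoint is used directly (ground speed
#' against the static scene); it sits on the pitch axis, so no correction is
#' needed. All derivatives are evaluated from the track's smoothing splines.
#'
#' @param strack a smoothed, calibrated track.
#' @param landmark `"tail"` (aquatic) or `"midpoint"` (aerial).
#' @param pitch_correction subtract the pitch-induced component (tail only).
#' @param segments optional; when given, per-wingbeat mean speeds are
#'   returned as well.
#' @return list with `series` (per-frame corrected along-path velocity),
#'   `mean`, `sd` (over wingbeats when `segments` is given, else over
#'   frames), `per_wingbeat`, and — for pitch-corrected tail estimates —
#'   `pitch_component_mean`, the mean magnitude of the removed
#'   pitch-induced velocity.
#' @export
translational_velocity <- function(strack, landmark = c("tail", "midpoint"),
                                   pitch_correction = TRUE, segments = NULL) {
  landmark <- match.arg(landmark)
  t <- track_time(strack)
  if (length(t) < 3) stop("need at least 3 frames for a velocity", call. = FALSE)
  if (landmark == "midpoint") {
    v <- (sm_xy(strack, "eye", t, deriv = 1) +
            sm_xy(strack, "tail", t, deriv = 1)) / 2
    vx <- v[, 1]
  } else {
    v_tail <- sm_xy(strack, "tail", t, deriv = 1)
    if (isTRUE(pitch_correction)) {
      eye <- sm_xy(strack, "eye", t)
      tl <- sm_xy(strack, "tail", t)
      ax <- eye - tl
      phi <- atan2(ax[, 2], ax[, 1])
      phi <- unwrap_angle(phi)
      phidot <- splinefun(t, phi, method = "fmm")(t, deriv = 1)
      r <- (tl - eye) / 2                     # midpoint -> tail
      v_pitch <- cbind(-phidot * r[, 2], phidot * r[, 1])
      v_tail <- v_tail - v_pitch
      pitch_speed <- mean(sqrt(rowSums(v_pitch^2)))
    }
    vx <- v_tail[, 1]
  }
  out <- list(series = vx)
  if (landmark == "tail" && isTRUE(pitch_correction)) {
    out$pitch_component_mean <- pitch_speed
  }
  if (!is.null(segments)) {
    tm <- minima_times(segments)
    per_wb <- vapply(seq_len(length(tm) - 1), function(i) {
      sel <- t >= tm[i] & t <= tm[i + 1]
      mean(vx[sel])
    }, numeric(1))
    out$per_wingbeat <- per_wb
    out$mean <- mean(per_wb)
    out$sd <- if (length(per_wb) > 1) sd(per_wb) else 0
  } else {
    out$mean <- mean(vx)
    out$sd <- sd(vx)
  }
  out
}

unwrap_angle <- function(phi) {
  dphi <- diff(phi)
  jumps <- cumsum(c(0, round(dphi / (2 * pi))))
  phi - 2 * pi * jumps
}

# ---- Strouhal ----------------------------------------------------------------

#' Strouhal number
#'
#' `St = f A / U`: wingbeat frequency times wing excursion over forward
#' speed. Dimensionless; `A` and `U` must share length units.
#'
#' @param f wingbeat frequency (Hz).
#' @param A wing excursion (length).
#' @param U forward speed (length/s).
#' @return Strouhal number.
#' @export
strouhal <- function(f, A, U) {
  if (any(c(f, A, U) <= 0)) stop("Strouhal inputs must all be > 0", call. = FALSE)
  f * A / U
}

#' Propagated standard deviation of the Strouhal number
#'
#' Propagates the per-flight standard deviation of wing excursion through
#' `St = f A / U` with `f` and `U` held at their flight means:
#' `sd(St) = f sd(A) / U`.
#'
#' @param f mean wingbeat frequency (Hz).
#' @param A_sd standard deviation of excursion over wingbeats.
#' @param U mean forward speed.
#' @return standard deviation of St.
#' @export
strouhal_sd <- function(f, A_sd, U) {
  stopifnot(A_sd >= 0)
  f * A_sd / U
}

#' Strouhal range over a species' cruising airspeeds
#'
#' For aerial flights whose airspeed was not measured, brackets St with the
#' species' size-class cruising-speed prediction interval: `St` is decreasing
#' in `U`, so the lower bound uses `airspeed_high` and vice versa.
#'
#' @param f wingbeat frequency (Hz).
#' @param A_m wing excursion in meters (airspeeds are metric).
#' @param species species label present in the configuration.
#' @param species_config from [load_species_config()].
#' @return list with `st_low` and `st_high`.
#' @export
strouhal_airspeed_range <- function(f, A_m, species, species_config) {
  row <- species_config[species_config$species == species, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("species '", species, "' not found in species config", call. = FALSE)
  }
  list(st_low = strouhal(f, A_m, row$airspeed_high),
       st_high = strouhal(f, A_m, row$airspeed_low))
}
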