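#' Summarise one flight into per-flight kinematics
#'
#' Aggregates per-wingbeat quantities into the flight-level record that is
#' the unit of all downstream statistics: means and SDs over wingbeats of
#' frequency, excursion, translational velocity and stroke-plane angle;
#' chord angles at mid-half-stroke; Strouhal number with the excursion SD
#' propagated; and, for parallel-view flights, wingbeat amplitude and stroke
#' velocities.
#'
#' @param strack a smoothed track from [smooth_track()] (calibrated for
#'   perpendicular views).
#' @param segments half-strokes from [segment_wingbeats()].
#' @param species_config optional table from [load_species_config()]; enables
#'   metric conversion and airspeed-based St for aerial flights.
#' @param params see [analysis_params()].
#' @return one-row tibble, or `NULL` (with a log entry) if the flight has no
#'   usable complete wingbeat.
#' @export
summarize_flight <- function(strack, segments, species_config = NULL,
                             params = analysis_params()) {
  id <- strack$flight_id
  n_wb <- length(minima_times(segments)) - 1
  if (n_wb < 1) {
    ak_log("dropped: zero usable wingbeats", flight_id = id)
    return(NULL)
  }
  row <- tibble::tibble(
    flight_id = id, species = strack$species, fluid = strack$fluid,
    view = strack$view,
    flight_class = strack$flight_class %||%
      (if (strack$fluid == "air") "aerial" else "unclassified"),
    size_class = NA_character_,
    descent_angle_deg = strack$descent_angle %||% NA_real_,
    n_wingbeats = n_wb,
    f_hz = NA_real_, f_sd = NA_real_, A_bl = NA_real_, A_sd_bl = NA_real_,
    A_m = NA_real_, U_bls = NA_real_, U_sd_bls = NA_real_, U_ms = NA_real_,
    beta_deg = NA_real_, beta_sd = NA_real_,
    alpha_up_deg = NA_real_, alpha_down_deg = NA_real_,
    amplitude_deg = NA_real_, amplitude_sd = NA_real_,
    stroke_vel_up = NA_real_, stroke_vel_down = NA_real_,
    st = NA_real_, st_sd = NA_real_,
    st_air_low = NA_real_, st_air_high = NA_real_
  )
  if (!is.null(species_config)) {
    sc <- species_config[species_config$species == strack$species, ]
    if (nrow(sc) == 1) row$size_class <- sc$size_class
  }

  if (strack$view == "perpendicular") {
    freq_mode <- if (strack$fluid == "water") "per_wingbeat" else "per_flight"
    f_wb <- wingbeat_frequency(segments, "per_wingbeat")
    f_mean <- if (freq_mode == "per_flight") {
      wingbeat_frequency(segments, "per_flight")
    } else mean(f_wb)
    exc <- wing_excursion(segments)
    beta <- stroke_plane_angle(strack, segments)
    vel <- translational_velocity(
      strack,
      landmark = if (strack$fluid == "water") "tail" else "midpoint",
      pitch_correction = isTRUE(params$pitch_correction),
      segments = segments
    )
    row$f_hz <- f_mean
    row$f_sd <- if (length(f_wb) > 1) sd(f_wb) else 0
    row$A_bl <- mean(exc)
    row$A_sd_bl <- if (length(exc) > 1) sd(exc) else 0
    row$U_bls <- vel$mean
    row$U_sd_bls <- vel$sd
    row$beta_deg <- mean(beta)
    row$beta_sd <- if (length(beta) > 1) sd(beta) else 0
    if (row$U_bls > 0) {
      row$st <- strouhal(row$f_hz, row$A_bl, row$U_bls)
      row$st_sd <- strouhal_sd(row$f_hz, row$A_sd_bl, row$U_bls)
    }
    if (strack$fluid == "water" &&
        all(c("wrist", "wingtip") %in% track_landmarks(strack))) {
      ca <- chord_angle(strack, segments)
      row$alpha_up_deg <- mean(ca$alpha_deg[ca$half_stroke == "upstroke"])
      row$alpha_down_deg <- mean(ca$alpha_deg[ca$half_stroke == "downstroke"])
    }
    if (!is.null(species_config)) {
      bl_m <- species_body_length_m(strack$species, species_config)
      row$A_m <- row$A_bl * bl_m
      row$U_ms <- row$U_bls * bl_m
      if (strack$fluid == "air") {
        rng <- strouhal_airspeed_range(row$f_hz, row$A_m, strack$species,
                                       species_config)
        row$st_air_low <- rng$st_low
        row$st_air_high <- rng$st_high
      }
    }
  } else {
    # parallel view: amplitude and stroke velocity
    amp <- vapply(seq_len(nrow(segments)), function(i) {
      s <- segments[i, ]
      t_max <- if (s$half_stroke == "upstroke") s$t_end else s$t_start
      t_min <- if (s$half_stroke == "upstroke") s$t_start else s$t_end
      wingbeat_amplitude_deg(
        shoulder = colMeans(sm_xy(strack, "shoulder", c(t_max, t_min))),
        wrist_at_max = sm_xy(strack, "wrist", t_max)[1, ],
        wrist_at_min = sm_xy(strack, "wrist", t_min)[1, ]
      )
    }, numeric(1))
    f_flight <- wingbeat_frequency(segments, "per_flight")
    dur <- if (identical(params$stroke_velocity_mode, "approx")) {
      rep(0.5 / f_flight, nrow(segments))
    } else {
      segments$duration
    }
    sv <- stroke_velocity(amp, dur)
    up <- segments$half_stroke == "upstroke"
    row$f_hz <- f_flight
    row$f_sd <- sd(wingbeat_frequency(segments, "per_wingbeat"))
    row$amplitude_deg <- mean(amp)
    row$amplitude_sd <- if (length(amp) > 1) sd(amp) else 0
    row$stroke_vel_up <- mean(sv[up])
    row$stroke_vel_down <- mean(sv[!up])
  }
  row
}

#' Analyse one flight end to end
#'
#' Runs the full per-flight pipeline: validation; descent-angle estimation
#' and trajectory classification (aquatic flights in the 10-20 deg gap are
#' excluded); path-frame rotation for descending flights; body-length
#' self-calibration (smoothed eye-tail series); kinematic smoothing;
#' wingbeat segmentation; and flight-level summary.
#'
#' @param track a `landmark_track`.
#' @param species_config optional, see [summarize_flight()].
#' @param params see [analysis_params()].
#' @param verbose log progress to stderr.
#' @return one-row tibble of flight kinematics, or `NULL` if the flight is
#'   excluded (unclassifiable trajectory or no usable wingbeats).
#' @export
analyze_flight <- function(track, species_config = NULL,
                           params = analysis_params(), verbose = FALSE) {
  validate_landmark_track(track)
  id <- track$flight_id

  if (track$view == "parallel") {
    strack <- smooth_track(track, params)
    elev <- landmark_xy(strack, "wrist")[, 2] - landmark_xy(strack, "shoulder")[, 2]
    segments <- segment_wingbeats(elev, track$frame_rate,
                                  params$prominence_fraction,
                                  time = track_time(strack))
    return(summarize_flight(strack, segments, species_config, params))
  }

  theta <- estimate_descent_angle(track)
  cls <- classify_flight(theta, track$fluid, params)
  ak_log(sprintf("descent %.1f deg -> %s", theta, cls),
         flight_id = id, verbose = verbose)
  if (cls == "unclassified") {
    ak_log("excluded: trajectory between horizontal and descending classes",
           flight_id = id)
    return(NULL)
  }
  rtrack <- if (cls == "descending_aquatic") {
    rotate_to_path_frame(track, theta)
  } else {
    track
  }
  t <- track_time(rtrack)
  bl_raw <- body_length_series(rtrack)
  bl_s <- fit_smoother(t, bl_raw, p = params$p_bodylength)$predict(t)
  ptrack <- calibrate_to_body_lengths(rtrack, bl_s,
                                      descent_angle = theta, flight_class = cls)
  strack <- smooth_track(ptrack, params)
  wl <- wing_landmark(strack)
  # elevation relative to the per-frame eye-tail average, strongly smoothed
  # so head movement and image drift cannot enter the reference
  elev_ref <- strack$center_smoother$y$predict(t)
  elev <- landmark_xy(strack, wl)[, 2] - elev_ref
  segments <- segment_wingbeats(elev, strack$frame_rate,
                                params$prominence_fraction, time = t)
  summarize_flight(strack, segments, species_config, params)
}

#' Analyse a batch of flights
#'
#' @param tracks list of `landmark_track` objects.
#' @inheritParams analyze_flight
#' @return tibble with one row per retained flight.
#' @export
analyze_flights <- function(tracks, species_config = NULL,
                            params = analysis_params(), verbose = FALSE) {
  rows <- lapply(tracks, function(tr) {
    tryCatch(analyze_flight(tr, species_config, params, verbose),
             error = function(e) {
               ak_log("failed: ", conditionMessage(e), flight_id = tr$flight_id)
               NULL
             })
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}
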