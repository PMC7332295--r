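#' Write a landmark track as a DLTdv-style CSV
#'
#' One row per frame, columns `pt<k>_cam1_X` / `pt<k>_cam1_Y` with landmarks
#' numbered in the order eye, tail, shoulder, wrist, wingtip (only the
#' landmarks present in the track are written). A sidecar metadata file
#' (`<path>.meta.yaml`, plain key-value text) stores species, fluid, view,
#' frame rate, flight id and, for synthetic tracks, the ground truth.
#'
#' @param track a `landmark_track`.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(track, path, sidecar = TRUE) {
  present <- track_landmarks(track)
  idx <- match(present, LANDMARKS)
  out <- data.frame(frame = track$data$frame)
  for (k in seq_along(present)) {
    out[[sprintf("pt%d_cam1_X", idx[k])]] <- track$data[[paste0(present[k], "_x")]]
    out[[sprintf("pt%d_cam1_Y", idx[k])]] <- track$data[[paste0(present[k], "_y")]]
  }
  write.csv(out, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(
      flight_id = track$flight_id, species = track$species,
      fluid = track$fluid, view = track$view, frame_rate = track$frame_rate
    )
    if (!is.null(track$ground_truth)) {
      gt <- track$ground_truth
      gt$origin_px <- as.list(gt$origin_px)
      meta$ground_truth <- gt
    }
    yaml::write_yaml(meta, sidecar_path(path), precision = 12)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.yaml")

#' Read a DLTdv-style landmark CSV
#'
#' Parses `pt<k>_cam1_X/Y` columns (landmark order: eye, tail, shoulder,
#' wrist, wingtip; any subset). Undigitized frames may hold NaN: interior
#' gaps shorter than `max_gap` frames are linearly interpolated with a
#' warning; longer gaps split the flight into separately returned segments.
#' Screen coordinates (y increasing downward) are flipped on ingest when
#' `y_down = TRUE`; internally y always increases upward.
#'
#' @param path CSV file.
#' @param metadata named list (`species`, `fluid`, `view`, `frame_rate`,
#'   `flight_id`); taken from the `.meta.yaml` sidecar when `NULL`.
#' @param y_down set `TRUE` if the file is in screen coordinates.
#' @param max_gap longest NaN run (frames) repaired by interpolation.
#' @param verbose log gap handling to stderr.
#' @return a `landmark_track`, or a list of them if long gaps split the
#'   flight.
#' @export
read_landmark_csv <- function(path, metadata = NULL, y_down = FALSE,
                              max_gap = 2, verbose = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(metadata)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop("no metadata given and no sidecar found at ", sc, call. = FALSE)
    }
    metadata <- yaml::read_yaml(sc)
  }
  raw <- read.csv(path, check.names = FALSE)
  frame <- if ("frame" %in% names(raw)) raw$frame else seq_len(nrow(raw)) - 1L
  if (is.unsorted(frame, strictly = TRUE)) {
    stop("non-monotone frame indices in ", path, call. = FALSE)
  }
  d <- tibble::tibble(frame = as.integer(frame))
  found <- character()
  for (k in seq_along(LANDMARKS)) {
    cx <- sprintf("pt%d_cam1_X", k)
    cy <- sprintf("pt%d_cam1_Y", k)
    if (cx %in% names(raw) && cy %in% names(raw)) {
      x <- as.numeric(raw[[cx]])
      y <- as.numeric(raw[[cy]])
      if (y_down) y <- -y
      d[[paste0(LANDMARKS[k], "_x")]] <- x
      d[[paste0(LANDMARKS[k], "_y")]] <- y
      found <- c(found, LANDMARKS[k])
    }
  }
  if (length(found) == 0) {
    stop("no landmark columns (pt<k>_cam1_X/Y) found in ", path, call. = FALSE)
  }
  make_track <- function(dd, id) {
    landmark_track(dd, frame_rate = metadata$frame_rate,
                   species = metadata$species %||% "unknown",
                   fluid = metadata$fluid %||% "water",
                   view = metadata$view %||% "perpendicular",
                   flight_id = id,
                   ground_truth = metadata$ground_truth)
  }
  id <- metadata$flight_id %||% basename(path)

  coord <- as.matrix(d[, -1, drop = FALSE])
  bad <- rowSums(!is.finite(coord)) > 0
  runs <- na_runs(if (any(bad)) ifelse(bad, NA_real_, 1) else rep(1, nrow(d)))
  long_gaps <- runs[runs$is_na & runs$length > max_gap, , drop = FALSE]
  short_gaps <- runs[runs$is_na & runs$length <= max_gap, , drop = FALSE]
  interp_cols <- function(dd) {
    for (cl in setdiff(names(dd), "frame")) {
      v <- dd[[cl]]
      if (anyNA(v) || any(!is.finite(v))) {
        v[!is.finite(v)] <- NA_real_
        dd[[cl]] <- stats::approx(dd$frame, v, xout = dd$frame, rule = 2)$y
      }
    }
    dd
  }
  if (nrow(short_gaps) > 0) {
    warning(sprintf("%s: interpolated %d short undigitized gap(s)", id,
                    nrow(short_gaps)), call. = FALSE)
  }
  if (nrow(long_gaps) == 0) {
    return(make_track(interp_cols(d), id))
  }
  # long undigitized runs split the flight into separate segments
  ak_log(sprintf("splitting on %d gap(s) of > %d frames", nrow(long_gaps), max_gap),
         flight_id = id, verbose = verbose)
  gap_starts <- long_gaps$start
  seg_id <- vapply(seq_len(nrow(d)), function(i) sum(gap_starts <= i), 0L)
  in_long_gap <- unlist(mapply(function(s, l) seq(s, s + l - 1),
                               long_gaps$start, long_gaps$length,
                               SIMPLIFY = FALSE))
  keep <- setdiff(seq_len(nrow(d)), in_long_gap)
  segs <- split(d[keep, , drop = FALSE], seg_id[keep])
  segs <- segs[vapply(segs, nrow, 1L) >= 2]
  out <- lapply(seq_along(segs), function(i) {
    make_track(interp_cols(segs[[i]]), sprintf("%s_s%d", id, i))
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a species configuration table
#'
#' One row per species with the quantities needed for metric conversion and
#' airspeed-based Strouhal ranges: `species`, `culmen_length_m`,
#' `culmen_to_body_ratio`, `size_class` (`medium` or `large`), and the
#' cruising-airspeed prediction bounds `airspeed_low` / `airspeed_high`
#' (m/s). Bounds may instead be given as `airspeed_mean` / `airspeed_sd`, in
#' which case `mean +/- 1.96 sd` is used.
#'
#' @param path CSV file; `NULL` loads the synthetic example configuration
#'   shipped with the package.
#' @return validated tibble.
#' @export
load_species_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_config_synthetic.csv",
                        package = "alcidkin")
  }
  cfg <- tibble::as_tibble(read.csv(path))
  need <- c("species", "culmen_length_m", "culmen_to_body_ratio", "size_class")
  if (!all(need %in% names(cfg))) {
    stop("species config lacks columns: ",
         paste(setdiff(need, names(cfg)), collapse = ", "), call. = FALSE)
  }
  if (!all(c("airspeed_low", "airspeed_high") %in% names(cfg))) {
    if (!all(c("airspeed_mean", "airspeed_sd") %in% names(cfg))) {
      stop("species config needs airspeed_low/high or airspeed_mean/sd",
           call. = FALSE)
    }
    b <- airspeed_bounds(cfg$airspeed_mean, cfg$airspeed_sd)
    cfg$airspeed_low <- b$low
    cfg$airspeed_high <- b$high
  }
  if (any(cfg$culmen_length_m <= 0) || any(cfg$culmen_to_body_ratio <= 0)) {
    stop("culmen length and ratio must be > 0", call. = FALSE)
  }
  if (any(cfg$airspeed_low >= cfg$airspeed_high)) {
    stop("airspeed_low must be < airspeed_high", call. = FALSE)
  }
  cfg
}

#' Airspeed prediction bounds from a mean and SD
#'
#' `mean +/- z * sd`, the 95 percent prediction interval for `z = 1.96`; used
#' to bracket the cruising airspeed of birds whose speed was not measured
#' directly.
#'
#' @param mean,sd cruising airspeed mean and SD (m/s).
#' @param z multiplier (default 1.96).
#' @return list with `low` and `high`.
#' @export
airspeed_bounds <- function(mean, sd, z = 1.96) {
  list(low = mean - z * sd, high = mean + z * sd)
}

results_columns <- c(
  "flight_id", "species", "fluid", "view", "flight_class", "size_class",
  "descent_angle_deg", "n_wingbeats", "f_hz", "f_sd", "A_bl", "A_sd_bl",
  "A_m", "U_bls", "U_sd_bls", "U_ms", "beta_deg", "beta_sd",
  "alpha_up_deg", "alpha_down_deg", "amplitude_deg", "amplitude_sd",
  "stroke_vel_up", "stroke_vel_down", "st", "st_sd",
  "st_air_low", "st_air_high"
)

#' Write the tidy per-flight results table
#'
#' One row per flight with a stable column order (identifiers, counts, then
#' frequency, excursion, velocity, angles, amplitude, stroke velocities and
#' Strouhal numbers). Round-trips through [read_results_table()] to at least
#' six decimals.
#'
#' @param records tibble of per-flight kinematics (rows from
#'   [summarize_flight()]); must be nonempty.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty results collection: nothing to write", call. = FALSE)
  }
  for (cl in setdiff(results_columns, names(records))) records[[cl]] <- NA
  write.csv(records[, results_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-flight results table
#' @param path CSV written by [write_results_table()].
#' @return tibble.
#' @export
read_results_table <- function(path) {
  tibble::as_tibble(read.csv(path))
}
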