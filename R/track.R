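#' Landmark names understood by the package
#'
#' Landmarks are digitized in this order in DLTdv-style files: eye, tail
#' (distal tip), shoulder, wrist, wingtip.
#'
#' @export
LANDMARKS <- c("eye", "tail", "shoulder", "wrist", "wingtip")

landmark_cols <- function(landmarks = LANDMARKS) {
  as.vector(rbind(paste0(landmarks, "_x"), paste0(landmarks, "_y")))
}

#' Construct a landmark track
#'
#' The raw-input container of the package: per-frame 2-D positions (pixels,
#' y increasing upward) of up to five anatomical landmarks, together with the
#' camera frame rate and per-flight metadata. A perpendicular-view track must
#' carry eye, tail, and wrist and/or wingtip; a parallel-view track must carry
#' shoulder and wrist.
#'
#' @param data data frame with a `frame` column (0-based, strictly increasing
#'   integers) and `<landmark>_x` / `<landmark>_y` columns for the landmarks
#'   present.
#' @param frame_rate frames per second (> 0).
#' @param species species label.
#' @param fluid `"air"` or `"water"`.
#' @param view `"perpendicular"` or `"parallel"` to the flight path.
#' @param flight_id identifier used in logs and result tables.
#' @param ground_truth optional list of generating parameters (synthetic
#'   tracks only); carried as a sidecar, never consumed by the estimators.
#' @return an object of class `landmark_track`.
#' @export
landmark_track <- function(data, frame_rate, species = "unknown",
                           fluid = c("water", "air"),
                           view = c("perpendicular", "parallel"),
                           flight_id = "flight", ground_truth = NULL) {
  fluid <- match.arg(fluid)
  view <- match.arg(view)
  track <- structure(
    list(
      data = tibble::as_tibble(data),
      frame_rate = frame_rate,
      species = species,
      fluid = fluid,
      view = view,
      flight_id = flight_id,
      ground_truth = ground_truth
    ),
    class = "landmark_track"
  )
  validate_landmark_track(track)
}

#' Validate a landmark track
#'
#' Checks the structural invariants: at least two frames, positive frame rate,
#' no duplicated frame indices, monotone frames, and the landmarks required by
#' the declared camera view.
#'
#' @param track a `landmark_track`.
#' @return the track, invisibly unchanged, or an error.
#' @export
validate_landmark_track <- function(track) {
  stopifnot(inherits(track, "landmark_track"))
  d <- track$data
  if (!is.numeric(track$frame_rate) || track$frame_rate <= 0) {
    stop("frame_rate must be > 0", call. = FALSE)
  }
  if (!"frame" %in% names(d)) stop("track data needs a 'frame' column", call. = FALSE)
  if (nrow(d) < 2) stop("a track needs at least 2 frames", call. = FALSE)
  if (anyDuplicated(d$frame)) stop("duplicated frame indices", call. = FALSE)
  if (is.unsorted(d$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  present <- track_landmarks(track)
  if (track$view == "perpendicular") {
    need <- c("eye", "tail")
    if (!all(need %in% present)) {
      stop("perpendicular view requires landmarks: ",
           paste(setdiff(need, present), collapse = ", "), call. = FALSE)
    }
    if (!any(c("wrist", "wingtip") %in% present)) {
      stop("perpendicular view requires wrist and/or wingtip", call. = FALSE)
    }
  } else {
    need <- c("shoulder", "wrist")
    if (!all(need %in% present)) {
      stop("parallel view requires landmarks: ",
           paste(setdiff(need, present), collapse = ", "), call. = FALSE)
    }
  }
  invisible(track)
}

#' Landmarks present in a track
#' @param track a `landmark_track`.
#' @return character vector, subset of [LANDMARKS].
#' @export
track_landmarks <- function(track) {
  nm <- names(track$data)
  LANDMARKS[paste0(LANDMARKS, "_x") %in% nm & paste0(LANDMARKS, "_y") %in% nm]
}

#' Per-frame times of a track
#' @param track a `landmark_track`.
#' @return numeric vector, `frame / frame_rate` in seconds.
#' @export
track_time <- function(track) track$data$frame / track$frame_rate

#' Extract one landmark as an n x 2 matrix
#' @param track a `landmark_track`.
#' @param landmark one of [LANDMARKS].
#' @return two-column matrix (x, y).
#' @export
landmark_xy <- function(track, landmark) {
  landmark <- match.arg(landmark, LANDMARKS)
  cols <- paste0(landmark, c("_x", "_y"))
  if (!all(cols %in% names(track$data))) {
    stop("landmark '", landmark, "' not present in track ", track$flight_id,
         call. = FALSE)
  }
  cbind(track$data[[cols[1]]], track$data[[cols[2]]])
}

# Replace coordinate columns with a transformed copy (same landmarks).
set_landmark_xy <- function(track, landmark, xy) {
  cols <- paste0(landmark, c("_x", "_y"))
  track$data[[cols[1]]] <- xy[, 1]
  track$data[[cols[2]]] <- xy[, 2]
  track
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf(
    "<landmark_track %s> %s, %s, %s view; %d frames @ %.2f fps; landmarks: %s\n",
    x$flight_id, x$species, x$fluid, x$view, nrow(x$data), x$frame_rate,
    paste(track_landmarks(x), collapse = ", ")
  ))
  invisible(x)
}

#' Eye-tail body midpoint of each frame
#'
#' The body reference point used for the mean path and for pitch correction:
#' the average of the eye and tail-tip positions. Using the midpoint rather
#' than the eye alone halves the leverage of wingbeat-synchronised head
#' movement on the estimated path.
#'
#' @param track a `landmark_track` (or path-frame track) carrying eye and tail.
#' @return n x 2 matrix.
#' @export
body_midpoint <- function(track) {
  (landmark_xy(track, "eye") + landmark_xy(track, "tail")) / 2
}
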