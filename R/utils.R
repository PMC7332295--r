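#' @importFrom stats anova aov coef lm pt ptukey qtukey rnorm sd smooth.spline
#'   splinefun var predict TukeyHSD setNames complete.cases median
#' @importFrom utils read.csv write.csv head tail
#' @importFrom rlang .data
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two 2-D vectors
#'
#' Unsigned angle in `[0, 180]` degrees, via the arc-cosine of the normalised
#' dot product. Used for chord angles and wingbeat amplitudes.
#'
#' @param a,b numeric length-2 vectors.
#' @return angle in degrees.
#' @keywords internal
angle_between <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("angle_between(): zero-length vector", call. = FALSE)
  }
  cosang <- sum(a * b) / (na * nb)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

# Counter-clockwise rotation of an n x 2 matrix of points (y-up convention).
rotate_points <- function(xy, angle_deg) {
  th <- deg2rad(angle_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy %*% t(R)
}

# Evaluate a run of repeated NA/finite states; returns rle on is.na.
na_runs <- function(x) {
  r <- rle(!is.finite(x))
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  data.frame(start = starts, length = r$lengths, is_na = r$values)
}

# Temporarily set the RNG seed, restoring global state on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stderr logging with a per-flight provenance prefix
ak_log <- function(..., flight_id = NULL, verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  prefix <- if (is.null(flight_id)) "[alcidkin]" else sprintf("[alcidkin %s]", flight_id)
  message(prefix, " ", ...)
  invisible(NULL)
}
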