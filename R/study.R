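#' Default synthetic study design
#'
#' One row per design cell (species x condition), with the per-cell means and
#' SDs from which individual flights are drawn. The defaults emulate a
#' four-species alcid study with three perpendicular-view conditions (aerial,
#' horizontal aquatic, descending aquatic) and two parallel-view conditions
#' (aerial, aquatic) per species. Effect structure baked into the defaults:
#' wingbeat frequency about 3x greater and stroke-plane angle about 13 deg
#' lower in air; wingbeat amplitude greater in water; Strouhal numbers in the
#' 0.13-0.29 range in water; upstroke chord angle increasing with descent.
#'
#' @param flights_per_cell flights drawn per design cell (>= 1).
#' @param species optional subset of the four default species.
#' @return tibble with one row per cell.
#' @export
default_study_design <- function(flights_per_cell = 3, species = NULL) {
  sp <- tibble::tibble(
    species = c("common_murre", "horned_puffin", "pigeon_guillemot", "tufted_puffin"),
    body_length_m = c(0.43, 0.33, 0.32, 0.38),
    f_water = c(2.4, 3.0, 3.2, 2.8),
    U_water = c(1.63, 1.5, 1.4, 1.5),       # m/s
    st_horizontal = c(0.18, 0.13, 0.15, 0.15),
    st_descending = c(0.24, 0.21, 0.29, 0.29),
    f_air = c(8.7, 7.5, 9.0, 7.8),
    U_air = c(16, 14.5, 15, 15),            # ground speed, m/s
    st_air = c(0.17, 0.22, 0.30, 0.27),
    amp_air = c(55, 57, 60, 55),
    amp_water = c(80, 82, 85, 78)
  )
  if (!is.null(species)) sp <- sp[sp$species %in% species, , drop = FALSE]
  if (nrow(sp) == 0) stop("empty design: no species selected", call. = FALSE)

  cell <- function(condition, fluid, view, f, U, st, amp, beta,
                   alpha_up, alpha_down, descent_lo, descent_hi, fps) {
    tibble::tibble(
      species = sp$species, body_length_m = sp$body_length_m,
      condition = condition, fluid = fluid, view = view,
      n_flights = flights_per_cell,
      f_mean = f, f_sd = 0.08 * f,
      U_mean = U, U_sd = 0.08 * U,
      A_mean = st * U / f, A_sd = 0.10 * st * U / f,
      beta_mean = beta, beta_sd = 4,
      alpha_up = alpha_up, alpha_down = alpha_down,
      amplitude_mean = amp, amplitude_sd = 0.06 * amp,
      descent_lo = descent_lo, descent_hi = descent_hi,
      frame_rate = fps
    )
  }
  dplyr::bind_rows(
    cell("horizontal_aquatic", "water", "perpendicular",
         sp$f_water, sp$U_water, sp$st_horizontal, NA,
         beta = 92, alpha_up = 15, alpha_down = 45,
         descent_lo = 0, descent_hi = 6, fps = 119.88),
    cell("descending_aquatic", "water", "perpendicular",
         sp$f_water, sp$U_water, sp$st_descending, NA,
         beta = 93, alpha_up = 45, alpha_down = 55,
         descent_lo = 25, descent_hi = 60, fps = 119.88),
    cell("aerial", "air", "perpendicular",
         sp$f_air, sp$U_air, sp$st_air, NA,
         beta = 79, alpha_up = 0, alpha_down = 0,
         descent_lo = 0, descent_hi = 0, fps = 239.76),
    cell("parallel_aerial", "air", "parallel",
         sp$f_air, sp$U_air, NA, sp$amp_air,
         beta = 79, alpha_up = 0, alpha_down = 0,
         descent_lo = 0, descent_hi = 0, fps = 239.76),
    cell("parallel_aquatic", "water", "parallel",
         sp$f_water, sp$U_water, NA, sp$amp_water,
         beta = 92, alpha_up = 0, alpha_down = 0,
         descent_lo = 0, descent_hi = 6, fps = 119.88)
  )
}

#' Generate a batch of synthetic flights from a study design
#'
#' Draws flight-level parameters from each design cell (normal draws for
#' frequency, speed, excursion, stroke-plane angle and amplitude; uniform
#' descent angles) and forward-simulates each flight. Ground truth, including
#' the cell's condition, rides along on every track.
#'
#' @param design tibble as returned by [default_study_design()]; must have at
#'   least one row and `n_flights >= 1` everywhere.
#' @param seed integer seed governing both the parameter draws and the
#'   per-flight digitization noise.
#' @param noise_sd pixels of digitization noise (0 = noise-free tracks);
#'   `NULL` gives each flight the generator's 1 percent body-length default.
#' @param head_bob_amp,pitch_amp perturbation defaults applied to aquatic
#'   perpendicular flights.
#' @param n_wingbeats wingbeats per flight.
#' @return list of `landmark_track` objects.
#' @export
generate_study_dataset <- function(design = default_study_design(),
                                   seed = 1L, noise_sd = NULL,
                                   head_bob_amp = 0.05, pitch_amp = 2,
                                   n_wingbeats = 5) {
  if (is.null(design) || nrow(design) == 0) {
    stop("empty design: nothing to generate", call. = FALSE)
  }
  if (any(design$n_flights < 1)) stop("flights per cell must be >= 1", call. = FALSE)
  with_seed(seed, {
    tracks <- list()
    for (i in seq_len(nrow(design))) {
      cl <- design[i, ]
      for (j in seq_len(cl$n_flights)) {
        f <- max(rnorm(1, cl$f_mean, cl$f_sd), 0.5 * cl$f_mean)
        U <- max(rnorm(1, cl$U_mean, cl$U_sd), 0.5 * cl$U_mean)
        descent <- stats::runif(1, cl$descent_lo, cl$descent_hi)
        perturb <- cl$view == "perpendicular" && cl$fluid == "water"
        p <- synthetic_flight_params(
          species_label = cl$species,
          fluid = cl$fluid,
          view = cl$view,
          body_length = cl$body_length_m,
          speed_U = U,
          descent_angle = descent,
          wingbeat_freq_f = f,
          excursion_A = if (is.finite(cl$A_mean)) {
            max(rnorm(1, cl$A_mean, cl$A_sd), 0.3 * cl$A_mean)
          } else 0.25 * cl$body_length_m,
          stroke_plane_beta = rnorm(1, cl$beta_mean, cl$beta_sd),
          chord_alpha_up = cl$alpha_up,
          chord_alpha_down = cl$alpha_down,
          amplitude_deg = if (is.finite(cl$amplitude_mean)) {
            rnorm(1, cl$amplitude_mean, cl$amplitude_sd)
          } else 80,
          head_bob_amp = if (perturb) head_bob_amp else 0,
          pitch_amp = if (perturb) pitch_amp else 0,
          noise_sd = noise_sd,
          frame_rate = cl$frame_rate,
          n_wingbeats = n_wingbeats,
          seed = sample.int(.Machine$integer.max, 1)
        )
        id <- sprintf("%s_%s_%02d", cl$species, cl$condition, j)
        tr <- generate_flight(p, flight_id = id)
        tr$ground_truth$condition <- cl$condition
        tracks[[id]] <- tr
      }
    }
    tracks
  })
}
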