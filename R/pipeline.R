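#' Default run configuration
#'
#' Controls an end-to-end simulate -> analyse -> statistics run.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole run.
#' @param flights_per_cell synthetic flights per design cell.
#' @param noise_sd digitization noise (pixels); `NULL` = generator default.
#' @param input_dir optional directory of landmark CSVs (with `.meta.yaml`
#'   sidecars) analysed instead of synthetic flights.
#' @param species_config_path species configuration CSV; `NULL` = packaged
#'   synthetic configuration.
#' @param bands efficiency bands for St: optimal propulsive band and the
#'   literature cruising-flight band.
#' @param params analysis parameters, see [analysis_params()].
#' @param make_figures write the St figure.
#' @return named list.
#' @export
run_config <- function(out_dir = tempfile("alcidkin_run_"), seed = 1L,
                       flights_per_cell = 3, noise_sd = NULL,
                       input_dir = NULL, species_config_path = NULL,
                       bands = list(optimal = c(0.2, 0.4),
                                    literature = c(0.12, 0.47)),
                       params = analysis_params(), make_figures = TRUE) {
  stopifnot(bands$optimal[1] < bands$optimal[2],
            bands$literature[1] < bands$literature[2])
  list(out_dir = out_dir, seed = seed, flights_per_cell = flights_per_cell,
       noise_sd = noise_sd, input_dir = input_dir,
       species_config_path = species_config_path, bands = bands,
       params = params, make_figures = make_figures)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a set of flights, analyses each into per-flight
#' kinematics, runs the statistical comparisons, and writes tidy CSV tables,
#' a run log and an St figure to `config$out_dir`. Deterministic under a
#' fixed seed.
#'
#' Outputs: `kinematics.csv` (per-flight records), `anova_st.csv` (St of
#' horizontal versus descending aquatic flight by species), `posthoc_st.csv`
#' (within-species Tukey contrasts), `anova_amplitude.csv` (parallel-view
#' amplitude air versus water), `posthoc_amplitude.csv`, `ttests.csv`
#' (within-species Welch tests of stroke velocity between fluids, with the
#' Bonferroni-adjusted alpha), `fig_strouhal.pdf`, `run.log`.
#'
#' @param config from [run_config()].
#' @return list with `kinematics`, `anova_st`, `posthoc_st`,
#'   `anova_amplitude`, `posthoc_amplitude`, `ttests`, `adjusted_alpha`,
#'   `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    ak_log(line, verbose = FALSE)
  }
  note("seed: %d", config$seed)

  species_config <- load_species_config(config$species_config_path)

  if (is.null(config$input_dir)) {
    design <- default_study_design(config$flights_per_cell)
    tracks <- generate_study_dataset(design, seed = config$seed,
                                     noise_sd = config$noise_sd)
    note("simulated %d flights from %d design cells", length(tracks), nrow(design))
  } else {
    files <- list.files(config$input_dir, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("meta", files)]
    if (length(files) == 0) stop("no landmark CSVs in ", config$input_dir, call. = FALSE)
    tracks <- list()
    for (f in files) {
      tr <- read_landmark_csv(f, verbose = FALSE)
      if (inherits(tr, "landmark_track")) tr <- list(tr)
      tracks <- c(tracks, tr)
    }
    note("read %d tracks from %s", length(tracks), config$input_dir)
  }

  kin <- analyze_flights(tracks, species_config, config$params)
  dropped <- setdiff(vapply(tracks, function(x) x$flight_id, ""), kin$flight_id)
  for (id in dropped) note("excluded flight: %s", id)
  note("analysed %d flights (%d excluded)", nrow(kin), length(dropped))
  files <- list(kinematics = file.path(config$out_dir, "kinematics.csv"))
  write_results_table(kin, files$kinematics)

  out <- list(kinematics = kin, files = files)

  # St: horizontal vs descending aquatic flight, by species
  aq <- dplyr::filter(kin, .data$fluid == "water",
                      .data$view == "perpendicular", is.finite(.data$st))
  if (length(unique(aq$flight_class)) > 1 && length(unique(aq$species)) > 1 &&
      nrow(aq) > length(unique(aq$species)) * length(unique(aq$flight_class)) + 1) {
    an_st <- fit_lm_sequential_anova(aq, "st", c("species", "flight_class"))
    out$anova_st <- an_st
    out$posthoc_st <- tukey_hsd(an_st, within = "species")
    files$anova_st <- file.path(config$out_dir, "anova_st.csv")
    files$posthoc_st <- file.path(config$out_dir, "posthoc_st.csv")
    write.csv(an_st$table, files$anova_st, row.names = FALSE)
    write.csv(out$posthoc_st, files$posthoc_st, row.names = FALSE)
    note("St ANOVA: flight-class eta^2 = %.3f",
         eta_squared(an_st)[["flight_class"]])
  }

  # amplitude: air vs water, parallel view
  par_ <- dplyr::filter(kin, .data$view == "parallel",
                        is.finite(.data$amplitude_deg))
  if (length(unique(par_$fluid)) > 1 && length(unique(par_$species)) > 1 &&
      nrow(par_) > length(unique(par_$species)) * length(unique(par_$fluid)) + 1) {
    an_amp <- fit_lm_sequential_anova(par_, "amplitude_deg", c("species", "fluid"))
    out$anova_amplitude <- an_amp
    out$posthoc_amplitude <- tukey_hsd(an_amp, within = "species")
    files$anova_amplitude <- file.path(config$out_dir, "anova_amplitude.csv")
    files$posthoc_amplitude <- file.path(config$out_dir, "posthoc_amplitude.csv")
    write.csv(an_amp$table, files$anova_amplitude, row.names = FALSE)
    write.csv(out$posthoc_amplitude, files$posthoc_amplitude, row.names = FALSE)
  }

  # stroke velocity: within-species Welch tests between fluids
  if (nrow(par_) > 0 && length(unique(par_$fluid)) > 1) {
    alpha_adj <- bonferroni_alpha(0.05, length(unique(par_$species)))
    tt <- list()
    for (sp in sort(unique(par_$species))) {
      for (side in c("stroke_vel_up", "stroke_vel_down")) {
        air <- par_[[side]][par_$species == sp & par_$fluid == "air"]
        wat <- par_[[side]][par_$species == sp & par_$fluid == "water"]
        if (length(air) >= 2 && length(wat) >= 2) {
          r <- welch_t_test(air, wat, paste(sp, "air"), paste(sp, "water"))
          r$response <- side
          r$adjusted_alpha <- alpha_adj
          tt[[paste(sp, side)]] <- r
        }
      }
    }
    if (length(tt) > 0) {
      out$ttests <- dplyr::bind_rows(tt)
      out$adjusted_alpha <- alpha_adj
      files$ttests <- file.path(config$out_dir, "ttests.csv")
      write.csv(out$ttests, files$ttests, row.names = FALSE)
      note("Welch tests at Bonferroni alpha = %.4f", alpha_adj)
    }
  }

  if (isTRUE(config$make_figures)) {
    fig <- plot_strouhal_by_flight(kin, config$bands)
    files$fig_strouhal <- file.path(config$out_dir, "fig_strouhal.pdf")
    ggplot2::ggsave(files$fig_strouhal, fig, width = 8, height = 5)
  }
  writeLines(c(log_lines, sprintf("excluded: %s",
                                  paste(dropped, collapse = ", "))), log_path)
  files$log <- log_path
  out$files <- files
  out
}

#' Classify a Strouhal number against efficiency bands
#'
#' Band membership with half-open intervals `[low, high)`: the optimal
#' propulsive band (0.2-0.4, where flapping-foil efficiency peaks) takes
#' precedence over the wider literature band for cruising birds (0.12-0.47).
#'
#' @param st Strouhal number(s), > 0.
#' @param bands list with `optimal` and `literature` interval edges.
#' @return character vector: `"inside_optimal"`, `"inside_literature"` or
#'   `"outside"`.
#' @export
classify_st_efficiency <- function(st, bands = list(optimal = c(0.2, 0.4),
                                                    literature = c(0.12, 0.47))) {
  stopifnot(all(st > 0))
  dplyr::case_when(
    st >= bands$optimal[1] & st < bands$optimal[2] ~ "inside_optimal",
    st >= bands$literature[1] & st < bands$literature[2] ~ "inside_literature",
    TRUE ~ "outside"
  )
}

#' Per-flight Strouhal figure
#'
#' One point per flight (mean St, +/- one propagated SD), grouped by species
#' and coloured by flight class, over the shaded optimal (0.2-0.4) and
#' literature (0.12-0.47) efficiency bands.
#'
#' @param results per-flight kinematics table.
#' @param bands see [classify_st_efficiency()].
#' @return a ggplot object.
#' @export
plot_strouhal_by_flight <- function(results,
                                    bands = list(optimal = c(0.2, 0.4),
                                                 literature = c(0.12, 0.47))) {
  d <- dplyr::filter(results, is.finite(.data$st))
  if (nrow(d) == 0) stop("no flights with a Strouhal number", call. = FALSE)
  d <- dplyr::arrange(d, .data$species, .data$flight_class, .data$flight_id)
  d$x <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$st)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = bands$literature[1], ymax = bands$literature[2],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = bands$optimal[1], ymax = bands$optimal[2],
                      alpha = 0.25, fill = "grey20") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$st - .data$st_sd,
                                        ymax = .data$st + .data$st_sd),
                           width = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flight_class), size = 2) +
    ggplot2::facet_grid(. ~ species, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "flight", y = "Strouhal number (fA/U)",
                  colour = "flight class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
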