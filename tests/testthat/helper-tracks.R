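# Shared fixtures: all tracks are generated in code at test time.

# A clean horizontal aquatic flight (no noise, no perturbations).
clean_params <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, head_bob_amp = 0, pitch_amp = 0),
                            list(...))
  do.call(synthetic_flight_params, args)
}

# A minimal hand-built perpendicular track: rigid body of length `bl` px
# translating at `vx` px/frame, wrist flapping sinusoidally `amp` px about
# the body axis.
toy_track <- function(n = 240, fps = 119.88, bl = 200, vx = 2, vy = 0,
                      amp = 25, f = 2.4, fluid = "water") {
  t <- (0:(n - 1)) / fps
  x0 <- vx * (0:(n - 1))
  y0 <- vy * (0:(n - 1))
  d <- tibble::tibble(
    frame = 0:(n - 1),
    eye_x = x0 + bl / 2, eye_y = y0,
    tail_x = x0 - bl / 2, tail_y = y0,
    wrist_x = x0, wrist_y = y0 + amp * sin(2 * pi * f * t),
    wingtip_x = x0 - 40, wingtip_y = y0 + amp * sin(2 * pi * f * t)
  )
  landmark_track(d, frame_rate = fps, fluid = fluid, flight_id = "toy")
}

# Deterministic per-flight analysis of a generated flight.
recover <- function(params, config = NULL) {
  analyze_flight(generate_flight(params), species_config = config)
}
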