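# shared fixtures, built in code at test time

OMEGA_10MHZ <- 2 * pi * 1e7 * 1e-9  # rad/ns at the 10 MHz study frequency

# small cohort configuration used across tests: 64 px keeps every sample
# region well above the 100-pixel draw while staying fast
test_cohort_config <- function(mode = "tissue", ...) {
  cohort_config(mode = mode, image_size = 64L, ...)
}

# a noiseless, jitter-free, artifact-free configuration for exactness tests
exact_cohort_config <- function(mode = "tissue", vessel_fraction = 0, ...) {
  cohort_config(mode = mode, image_size = 48L, noise = "none",
                pixel_jitter_cv = 0, vessel_fraction = vessel_fraction, ...)
}

# uniform sinusoidal frame stack built independently of simulate_frames
sinusoid_stack <- function(phi, m, dc, config = flim_config(),
                           h = 2L, w = 2L, channel = "PPIX") {
  frames <- array(0, c(h, w, config$n_phase_steps))
  for (k in seq_len(config$n_phase_steps))
    frames[, , k] <- dc * (1 + m * cos(config$phase_offsets_rad[k] - phi))
  raw_frame_stack(frames, config, channel = channel)
}

# lifetime map built directly from a tau matrix
map_from_tau <- function(tau, channel = "PPIX", dc_value = 1000,
                         frequency_hz = 1e7) {
  lifetime_map(tau, valid = is.finite(tau),
               dc = matrix(dc_value, nrow(tau), ncol(tau)),
               channel = channel, frequency_hz = frequency_hz)
}

# memoized pipeline runs over seeded cohorts, shared by the acceptance
# criteria that use the same 25-cohort harness
.run_cache <- new.env(parent = emptyenv())
acceptance_runs <- function(mode, n_seeds = 25L) {
  key <- paste0(mode, "_", n_seeds)
  if (is.null(.run_cache[[key]])) {
    stages <- if (mode == "tissue") c("stats", "phasor") else "stats"
    .run_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      coh <- generate_cohort(test_cohort_config(mode = mode), seed = s)
      run_pipeline(coh, seed = s, stages = stages)
    })
  }
  .run_cache[[key]]
}

group_median <- function(run, key, group, col) {
  gs <- run$group_summaries[[key]]
  gs[gs$group == group, col]
}
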