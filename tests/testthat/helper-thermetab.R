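# Shared fixtures: small cohorts and trace configs used across test files.

small_cohort_config <- function(seed = 1, n_fish_total = 24, ...) {
  cohort_config(
    n_populations = 2,
    histories = c("ambient", "warm"),
    n_tanks_per_population = 2,
    n_fish_total = n_fish_total,
    seed = seed,
    ...
  )
}

# zero-noise cohort on the deterministic generative surfaces, no
# temperature-dependent exponent shift (the "all noise and offsets zero"
# identity setting)
identity_cohort_config <- function(seed = 1, n_fish = 24) {
  zero_noise(cohort_config(
    n_populations = 2,
    histories = c("ambient", "warm"),
    n_tanks_per_population = 2,
    n_fish_total = n_fish,
    mass_by_temperature_interaction = 0,
    seed = seed
  ))
}

clean_trace_config <- function(...) {
  trace_config(
    sensor_noise_sd = 0, burst_rate_per_h = 0,
    blank_rate_start = 0, blank_rate_end = 0,
    smr_duration_h = 2, ...
  )
}

estimates_from_truth <- function(cohort) {
  dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    summarize_metabolism(
      cohort$fish_id[i],
      smr = cohort$true_smr[i],
      rmr = cohort$true_rmr[i],
      mmr = cohort$true_mmr[i]
    )
  }))
}

measured_cohort <- function(cohort) {
  dplyr::rename(cohort, smr = "true_smr", rmr = "true_rmr", mmr = "true_mmr")
}
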