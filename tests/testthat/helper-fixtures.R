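# Shared fixtures: compact protocols and cohorts so individual tests stay
# fast; study-condition defaults are exercised in the acceptance tests.

short_protocol <- function(sampling_rate = 1000, n_fatigue = 0,
                           fatigue_gap = 3) {
  force_protocol(sampling_rate = sampling_rate, tetanus_duration = 2,
                 tetanic_gap = 4, fatigue_gap = fatigue_gap,
                 n_fatigue = n_fatigue, lead_in = 1, tail = 2)
}

tiny_gait_specs <- function(n_healthy = 8, n_grmd = 10) {
  list(cohort_spec("healthy", n_healthy), cohort_spec("grmd_ctrl", n_grmd))
}

# gait cohort-spec parameter override with all SDs zero
zero_sd_params <- function(group = "healthy") {
  pr <- grmdpheno:::group_gait_params(group)
  pr$sd[] <- 0
  pr
}
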