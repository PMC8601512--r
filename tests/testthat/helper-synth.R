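# Small cohort configurations used across tests: the study-calibrated
# defaults with the cohort scaled down so the suite stays fast.
small_config <- function(n_units = 10L, seed = 42L, ...) {
  cohort_config(n_units = n_units, admissions_per_occupied_bed = 10,
                seed = seed, ...)
}

# units table with smr/sru columns attached (what plant_frontier expects)
units_with_performance <- function(n_units = 10L, seed = 42L) {
  cfg <- small_config(n_units = n_units, seed = seed)
  units <- generate_units(cfg)
  units$smr <- stats::runif(n_units, 0.6, 1.6)
  units$sru <- stats::runif(n_units, 0.6, 1.8)
  units
}

# run all built-in models on a planted table; returns named list of reports
run_all_models <- function(units) {
  lapply(builtin_model_specs(), run_model, units = units, performance = NULL)
}
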