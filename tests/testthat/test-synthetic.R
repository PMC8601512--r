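# Synthetic cohort generator: validation, determinism, calibration and the
# planted-frontier construction.

test_that("configuration invariants are enforced with named errors", {
  expect_error(cohort_config(admin_weights = c(public = 0.5,
                                               philanthropic = 0.2,
                                               for_profit = 0.2)),
               "admin_weights")
  expect_error(cohort_config(mortality_calibration = 1.2),
               "mortality_calibration")
  expect_error(cohort_config(mortality_calibration = 0.3,
                             hospital_mortality_calibration = 0.2),
               "hospital_mortality_calibration")
  expect_error(cohort_config(saps3_scale = -1), "saps3_scale")
  expect_error(cohort_config(occupancy_shape1 = 0), "Beta")
  expect_error(cohort_config(n_units = 0), "n_units")
  expect_error(
    cohort_config(staffing_ratio_distributions = list(
      physicians = c(0.5, -1), nurses = c(0.5, 0.4),
      nursing_techs = c(1.6, 0.1), physios = c(0, 0.3))),
    "physicians")
})

test_that("generation is deterministic under the seed and varies across seeds", {
  cfg <- small_config(n_units = 8L, seed = 5L)
  u1 <- generate_units(cfg)
  u2 <- generate_units(cfg)
  expect_identical(u1, u2)
  p1 <- generate_patients(u1, cfg)
  p2 <- generate_patients(u1, cfg)
  expect_identical(p1, p2)
  cfg2 <- small_config(n_units = 8L, seed = 6L)
  expect_false(identical(generate_units(cfg2), u1))
  # byte-identical CSV output
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  for (f in c("units.csv", "patients.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("unit table respects its structural invariants", {
  cfg <- small_config(n_units = 40L, seed = 9L)
  u <- generate_units(cfg)
  expect_equal(nrow(u), 40L)
  ratio_cols <- c("physicians_per_10_beds", "nurses_per_10_beds",
                  "nursing_techs_per_10_beds", "physios_per_10_beds",
                  "physician_hours_week", "nurse_hours_week")
  expect_true(all(as.matrix(u[, ratio_cols]) > 0))
  expect_true(all(u$occupancy > 0 & u$occupancy <= 1))
  expect_true(all(u$bed_proportion > 0 & u$bed_proportion <= 1))
  expect_equal(u$bed_proportion, u$icu_beds / u$hospital_beds)
  expect_equal(u$hospital_size_category,
               hospital_size_category(u$hospital_beds))
  # single unit: derived field is the exact ratio
  u1 <- generate_units(small_config(n_units = 1L, seed = 2L))
  expect_equal(nrow(u1), 1L)
  expect_equal(u1$bed_proportion, u1$icu_beds / u1$hospital_beds)
})

test_that("default bed-count calibration puts the median in the published band", {
  meds <- vapply(1:5, function(s) {
    stats::median(generate_units(cohort_config(seed = s))$icu_beds)
  }, numeric(1))
  expect_true(all(meds >= 10 & meds <= 20))
})

test_that("patient table respects its structural invariants", {
  cfg <- small_config(n_units = 6L, seed = 21L)
  u <- generate_units(cfg)
  p <- generate_patients(u, cfg)
  expect_true(all(p$unit_id %in% u$unit_id))
  expect_true(all(p$saps3 >= 0))
  expect_true(all(p$icu_los > 0))
  expect_true(all(p$hospital_los >= p$icu_los))
  expect_true(all(p$hospital_death[p$icu_death]))  # icu death => hospital death
  expect_true(all(p$age >= 16))
  expect_error(generate_patients(u[0, ], cfg), "non-empty")
})

test_that("mortality calibration hits the target and the null model has SMR 1", {
  cfg <- cohort_config(n_units = 12L, unit_effect_sd = 0,
                       unit_los_effect_sd = 0,
                       admissions_per_occupied_bed = 120,
                       seed = 31L)
  sim <- simulate_cohort(cfg)
  p <- sim$patients
  n <- nrow(p)
  expect_gt(n, 10000)
  # pooled ICU mortality within 3 Monte-Carlo SE of the 12% target
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(mean(p$icu_death) - 0.12), 3 * se + 1e-12)
  se_h <- sqrt(0.18 * 0.82 / n)
  expect_lt(abs(mean(p$hospital_death) - 0.18), 3 * se_h + 1e-12)
  # with no unit effect, pooled SMR against the matching calibrated
  # equation is 1 up to Monte-Carlo error
  smr <- compute_smr(p, sim$coefficients_icu, outcome = "icu")
  pooled <- sum(smr$observed_deaths) / sum(smr$expected_deaths)
  expect_lt(abs(pooled - 1), 0.05)
})

test_that("a planted mortality multiplier is recovered by the realized SMR", {
  cfg <- cohort_config(n_units = 2L, unit_effect_sd = 0,
                       beds_bands = data.frame(lower = 60L, upper = 60L,
                                               weight = 1),
                       admissions_per_occupied_bed = 500,
                       seed = 41L)
  u <- generate_units(cfg)
  p <- generate_patients(u, cfg,
                         mortality_multipliers = c(U001 = 2.0))
  smr <- compute_smr(p, attr(p, "coefficients_icu"), outcome = "icu")
  planted <- smr[smr$unit_id == "U001", ]
  expect_gt(planted$n_admissions, 20000)
  # Monte-Carlo oracle: death probabilities are min(2 * risk, 1), so the
  # attainable SMR is sum(min(2p, 1)) / sum(p), just under 2 because a few
  # very severe admissions clip at probability 1
  base <- saps3_risk(p$saps3[p$unit_id == "U001"],
                     attr(p, "coefficients_icu"))
  risks <- pmin(2 * base, 1)
  expected_smr <- sum(risks) / sum(base)
  expect_lt(abs(expected_smr - 2), 0.1)
  se <- sqrt(sum(risks * (1 - risks))) / planted$expected_deaths
  expect_lt(abs(planted$smr - expected_smr), 3 * se)
  # the control unit stays near 1
  control <- smr[smr$unit_id == "U002", ]
  expect_lt(abs(control$smr - 1), 0.1)
})

test_that("planted frontier is recovered exactly by every built-in model", {
  u <- units_with_performance(n_units = 5L, seed = 51L)
  planted <- c("U002", "U004")
  pl <- plant_frontier(u, planted, dominance_margin = 0.2)
  for (rep in run_all_models(pl)) {
    eff <- rep$scores$unit_id[rep$scores$efficient]
    expect_setequal(eff, planted)
  }
  # all units planted: nothing is dominated, everything efficient
  all_pl <- plant_frontier(u, u$unit_id, dominance_margin = 0.2)
  for (rep in run_all_models(all_pl))
    expect_true(all(rep$scores$efficient))
  # preconditions
  expect_error(plant_frontier(u, character(0), 0.2), "non-empty")
  expect_error(plant_frontier(u, "U002", 0), "margin")
  expect_error(plant_frontier(u, "nope", 0.2), "subset")
})

test_that("planted-frontier recovery holds at 20 units and margin 0.1", {
  u <- units_with_performance(n_units = 20L, seed = 61L)
  planted <- c("U003", "U011", "U017")
  pl <- plant_frontier(u, planted, dominance_margin = 0.1)
  for (rep in run_all_models(pl))
    expect_setequal(rep$scores$unit_id[rep$scores$efficient], planted)
})
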