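#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles and validates every parameter of the generator. The defaults are
#' calibrated to the multicenter Brazilian ICU cohort the package targets:
#' 93 units, SAPS-3 centred at 44 with quartiles 34/54, pooled ICU mortality
#' 12\% and hospital mortality 18\%, ICU length of stay with median ~3 days
#' and quartiles ~1/6, bed occupancy with quartiles 0.75/0.83/0.87, and the
#' published distributions of bed counts, staffing ratios, weekly staffing
#' hours and organizational categories.
#'
#' @param n_units Number of ICUs to generate.
#' @param beds_bands Data frame with columns \code{lower}, \code{upper},
#'   \code{weight}: bed-count bands and their sampling weights (weights must
#'   be nonnegative and sum to 1).
#' @param saps3_location,saps3_scale Location and scale (score points) of the
#'   zero-truncated normal severity distribution.
#' @param mortality_calibration Target pooled ICU mortality (proportion in
#'   (0,1)); achieved by an intercept shift of the risk equation found by
#'   root-finding on the simulated severities.
#' @param hospital_mortality_calibration Target pooled hospital mortality;
#'   must be at least \code{mortality_calibration}.
#' @param los_meanlog,los_sdlog Marginal lognormal parameters of ICU length
#'   of stay (days).
#' @param los_severity_coef Increase of the LOS meanlog per standard
#'   deviation of SAPS-3 (must satisfy \code{los_severity_coef < los_sdlog};
#'   the residual lognormal scale is reduced so the marginal scale is kept).
#' @param staffing_ratio_distributions Named list (\code{physicians},
#'   \code{nurses}, \code{nursing_techs}, \code{physios}) of
#'   \code{c(meanlog, sdlog)} for the per-10-bed ratios.
#' @param hours_distributions Named list (\code{physician_hours},
#'   \code{nurse_hours}) of \code{c(meanlog, sdlog)} for weekly hours.
#' @param occupancy_shape1,occupancy_shape2 Beta parameters of bed occupancy
#'   (defaults from least-squares quantile matching to quartiles
#'   0.75/0.83/0.87).
#' @param admin_weights,icu_type_weights,hospital_size_weights Named
#'   nonnegative categorical weights summing to 1.
#' @param unit_effect_sd Standard deviation (log scale) of the between-unit
#'   mortality multiplier: 0 means every unit's true SMR is 1.
#' @param unit_los_effect_sd Standard deviation (log scale) of the
#'   between-unit LOS multiplier (drives SRU dispersion).
#' @param admissions_per_occupied_bed Expected admissions per occupied bed
#'   over the study window (default 88, chosen so the default 93-unit cohort
#'   reproduces roughly 130,000 admissions over a two-year window).
#' @param coefficients Baseline [saps3_coefficients()] the calibration
#'   shifts are applied to.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   tables.
#'
#' @return An object of class \code{"cohort_config"} (a validated list).
#' @export
cohort_config <- function(n_units = 93L,
                          beds_bands = data.frame(
                            lower = c(4L, 11L, 31L, 51L),
                            upper = c(10L, 30L, 50L, 80L),
                            weight = c(0.40, 0.48, 0.11, 0.01)),
                          saps3_location = 44,
                          saps3_scale = 15,
                          mortality_calibration = 0.12,
                          hospital_mortality_calibration = 0.18,
                          los_meanlog = 1.0,
                          los_sdlog = 1.2,
                          los_severity_coef = 0.3,
                          staffing_ratio_distributions = list(
                            physicians = c(meanlog = log(1.67), sdlog = 0.286),
                            nurses = c(meanlog = log(1.71), sdlog = 0.391),
                            nursing_techs = c(meanlog = log(5), sdlog = 0.148),
                            physios = c(meanlog = log(1), sdlog = 0.303)),
                          hours_distributions = list(
                            physician_hours = c(meanlog = log(372), sdlog = 0.447),
                            nurse_hours = c(meanlog = log(396), sdlog = 0.487)),
                          occupancy_shape1 = 14.76,
                          occupancy_shape2 = 3.48,
                          admin_weights = c(public = 17, philanthropic = 19,
                                            for_profit = 57) / 93,
                          icu_type_weights = c(mixed = 75, surgical = 8,
                                               medical = 1, neurological = 5,
                                               other = 4) / 93,
                          hospital_size_weights = c(small = 9, medium = 33,
                                                    large = 51) / 93,
                          unit_effect_sd = 0.25,
                          unit_los_effect_sd = 0.30,
                          admissions_per_occupied_bed = 88,
                          coefficients = saps3_coefficients(),
                          seed = 1L) {
  cfg <- list(n_units = as.integer(n_units), beds_bands = beds_bands,
              saps3_location = saps3_location, saps3_scale = saps3_scale,
              mortality_calibration = mortality_calibration,
              hospital_mortality_calibration = hospital_mortality_calibration,
              los_meanlog = los_meanlog, los_sdlog = los_sdlog,
              los_severity_coef = los_severity_coef,
              staffing_ratio_distributions = staffing_ratio_distributions,
              hours_distributions = hours_distributions,
              occupancy_shape1 = occupancy_shape1,
              occupancy_shape2 = occupancy_shape2,
              admin_weights = admin_weights,
              icu_type_weights = icu_type_weights,
              hospital_size_weights = hospital_size_weights,
              unit_effect_sd = unit_effect_sd,
              unit_los_effect_sd = unit_los_effect_sd,
              admissions_per_occupied_bed = admissions_per_occupied_bed,
              coefficients = coefficients,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

check_weights <- function(w, field) {
  if (any(!is.finite(w)) || any(w < 0))
    stop(sprintf("`%s` must be finite and nonnegative.", field))
  if (abs(sum(w) - 1) > 1e-8)
    stop(sprintf("`%s` must sum to 1 (got %.6f).", field, sum(w)))
  invisible(w)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_units < 1L) stop("`n_units` must be a positive integer.")
  bb <- cfg$beds_bands
  if (!all(c("lower", "upper", "weight") %in% names(bb)))
    stop("`beds_bands` needs columns lower, upper, weight.")
  if (any(bb$lower > bb$upper) || any(bb$lower < 1))
    stop("`beds_bands` bounds must satisfy 1 <= lower <= upper.")
  check_weights(bb$weight, "beds_bands$weight")
  check_weights(cfg$admin_weights, "admin_weights")
  check_weights(cfg$icu_type_weights, "icu_type_weights")
  check_weights(cfg$hospital_size_weights, "hospital_size_weights")
  if (cfg$saps3_scale <= 0) stop("`saps3_scale` must be > 0.")
  for (p in c("mortality_calibration", "hospital_mortality_calibration"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1)
      stop(sprintf("`%s` must lie in (0, 1).", p))
  if (cfg$hospital_mortality_calibration < cfg$mortality_calibration)
    stop("`hospital_mortality_calibration` must be >= `mortality_calibration`.")
  if (cfg$los_sdlog <= 0) stop("`los_sdlog` must be > 0.")
  if (cfg$los_severity_coef < 0 || cfg$los_severity_coef >= cfg$los_sdlog)
    stop("`los_severity_coef` must lie in [0, los_sdlog).")
  for (nm in c("physicians", "nurses", "nursing_techs", "physios")) {
    d <- cfg$staffing_ratio_distributions[[nm]]
    if (is.null(d) || length(d) != 2L || d[2L] <= 0)
      stop(sprintf("`staffing_ratio_distributions$%s` must be c(meanlog, sdlog > 0).", nm))
  }
  for (nm in c("physician_hours", "nurse_hours")) {
    d <- cfg$hours_distributions[[nm]]
    if (is.null(d) || length(d) != 2L || d[2L] <= 0)
      stop(sprintf("`hours_distributions$%s` must be c(meanlog, sdlog > 0).", nm))
  }
  if (cfg$occupancy_shape1 <= 0 || cfg$occupancy_shape2 <= 0)
    stop("occupancy Beta shapes must be > 0.")
  if (cfg$unit_effect_sd < 0) stop("`unit_effect_sd` must be >= 0.")
  if (cfg$unit_los_effect_sd < 0) stop("`unit_los_effect_sd` must be >= 0.")
  if (cfg$admissions_per_occupied_bed <= 0)
    stop("`admissions_per_occupied_bed` must be > 0.")
  if (!inherits(cfg$coefficients, "saps3_coefficients"))
    stop("`coefficients` must be a saps3_coefficients object.")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort config: %d units, seed %d\n",
              x$n_units, x$seed))
  cat(sprintf("  SAPS-3 ~ TN(%g, %g); ICU/hospital mortality targets %.0f%%/%.0f%%\n",
              x$saps3_location, x$saps3_scale,
              100 * x$mortality_calibration,
              100 * x$hospital_mortality_calibration))
  cat(sprintf("  LOS ~ lognormal(%g, %g); unit effect SDs %.2f (mortality) %.2f (LOS)\n",
              x$los_meanlog, x$los_sdlog, x$unit_effect_sd,
              x$unit_los_effect_sd))
  invisible(x)
}

sample_int_range <- function(n, lower, upper) {
  lower + floor(stats::runif(n) * (upper - lower + 1))
}

#' Generate the unit-level (ICU) table
#'
#' Draws \code{n_units} ICUs: bed counts from the configured bands, hospital
#' size category and bed count, staffing ratios and weekly hours (lognormal),
#' bed occupancy (Beta), administration and ICU type (categorical), plus the
#' derived fields \code{hospital_size_category} and \code{bed_proportion}.
#' Units are nested in hospitals (several ICUs may share a hospital and its
#' administration, size and bed count).
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per ICU (see package README for columns).
#' @export
generate_units <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_units
  # hospitals: roughly 0.6 hospitals per ICU, each with admin/size/beds
  n_hosp <- max(1L, ceiling(0.6 * n))
  hosp_size <- sample(names(config$hospital_size_weights), n_hosp,
                      replace = TRUE, prob = config$hospital_size_weights)
  hosp_beds <- integer(n_hosp)
  hosp_beds[hosp_size == "small"] <- sample_int_range(sum(hosp_size == "small"), 40L, 99L)
  hosp_beds[hosp_size == "medium"] <- sample_int_range(sum(hosp_size == "medium"), 100L, 200L)
  hosp_beds[hosp_size == "large"] <- sample_int_range(sum(hosp_size == "large"), 201L, 600L)
  hosp_admin <- sample(names(config$admin_weights), n_hosp, replace = TRUE,
                       prob = config$admin_weights)
  hid <- sample.int(n_hosp, n, replace = TRUE)

  band <- sample.int(nrow(config$beds_bands), n, replace = TRUE,
                     prob = config$beds_bands$weight)
  icu_beds <- sample_int_range(n, config$beds_bands$lower[band],
                               config$beds_bands$upper[band])
  hospital_beds <- pmax(hosp_beds[hid], icu_beds + 5L)  # ICU cannot exceed hospital

  srd <- config$staffing_ratio_distributions
  hd <- config$hours_distributions
  occupancy <- pmin(stats::rbeta(n, config$occupancy_shape1,
                                 config$occupancy_shape2), 1)
  units <- data.frame(
    unit_id = sprintf("U%03d", seq_len(n)),
    hospital_id = sprintf("H%03d", hid),
    icu_beds = icu_beds,
    hospital_beds = hospital_beds,
    physicians_per_10_beds = stats::rlnorm(n, srd$physicians[1L], srd$physicians[2L]),
    nurses_per_10_beds = stats::rlnorm(n, srd$nurses[1L], srd$nurses[2L]),
    nursing_techs_per_10_beds = stats::rlnorm(n, srd$nursing_techs[1L], srd$nursing_techs[2L]),
    physios_per_10_beds = stats::rlnorm(n, srd$physios[1L], srd$physios[2L]),
    physician_hours_week = stats::rlnorm(n, hd$physician_hours[1L], hd$physician_hours[2L]),
    nurse_hours_week = stats::rlnorm(n, hd$nurse_hours[1L], hd$nurse_hours[2L]),
    occupancy = occupancy,
    admin = hosp_admin[hid],
    icu_type = sample(names(config$icu_type_weights), n, replace = TRUE,
                      prob = config$icu_type_weights),
    stringsAsFactors = FALSE)
  units$hospital_size_category <- hospital_size_category(units$hospital_beds)
  units$bed_proportion <- units$icu_beds / units$hospital_beds
  units
}

#' Hospital size category from total hospital beds
#'
#' Small: fewer than 100 beds; medium: 100 to 200 beds inclusive; large: more
#' than 200 beds.
#' @param hospital_beds Integer vector.
#' @return Character vector in \{"small", "medium", "large"\}.
#' @export
hospital_size_category <- function(hospital_beds) {
  ifelse(hospital_beds < 100, "small",
         ifelse(hospital_beds <= 200, "medium", "large"))
}

#' Generate the patient-level (admission) table
#'
#' Simulates admissions for each unit: counts proportional to
#' beds x occupancy, SAPS-3 from a zero-truncated normal, death as a
#' Bernoulli draw with probability equal to the calibrated SAPS-3 risk times
#' a unit-level lognormal multiplier (clipped to 1), and ICU length of stay
#' from a lognormal whose location increases with severity and a unit-level
#' LOS multiplier. A single uniform draw per patient drives both death
#' indicators, so \code{icu_death} implies \code{hospital_death} and both
#' marginal calibrations hold. Hospital LOS adds a post-ICU ward stay for
#' ICU survivors.
#'
#' The ICU- and hospital-calibrated coefficient sets (the baseline equation
#' with the fitted intercept shifts) are attached as attributes
#' \code{"coefficients_icu"} and \code{"coefficients_hospital"}; computing an
#' SMR with the matching set yields a pooled SMR of ~1 under the null
#' (\code{unit_effect_sd = 0}). The realized unit multipliers are attached as
#' \code{"unit_multipliers"}.
#'
#' @param units A [generate_units()] table (non-empty).
#' @param config The same [cohort_config()].
#' @param mortality_multipliers,los_multipliers Optional named numeric
#'   vectors (names = unit ids) overriding the random unit-level multipliers;
#'   used to plant units with known true SMR/SRU.
#' @return Data frame with one row per admission: \code{patient_id},
#'   \code{unit_id}, \code{age}, \code{admission_type}, \code{saps3},
#'   \code{icu_los}, \code{hospital_los}, \code{icu_death},
#'   \code{hospital_death}.
#' @export
generate_patients <- function(units, config,
                              mortality_multipliers = NULL,
                              los_multipliers = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.data.frame(units) || nrow(units) == 0L)
    stop("`units` must be a non-empty data frame.")
  set.seed(config$seed + 1L)
  n_adm <- pmax(1L, as.integer(round(units$icu_beds * units$occupancy *
                                       config$admissions_per_occupied_bed)))
  N <- sum(n_adm)
  unit_id <- rep(units$unit_id, n_adm)

  # unit-level multiplicative effects (log-normal, mean log = 0)
  m_unit <- stats::setNames(stats::rlnorm(nrow(units), 0, config$unit_effect_sd),
                            units$unit_id)
  l_unit <- stats::setNames(stats::rlnorm(nrow(units), 0, config$unit_los_effect_sd),
                            units$unit_id)
  if (!is.null(mortality_multipliers)) {
    if (is.null(names(mortality_multipliers)) ||
        !all(names(mortality_multipliers) %in% units$unit_id))
      stop("`mortality_multipliers` must be named by unit id.")
    m_unit[names(mortality_multipliers)] <- mortality_multipliers
  }
  if (!is.null(los_multipliers)) {
    if (is.null(names(los_multipliers)) ||
        !all(names(los_multipliers) %in% units$unit_id))
      stop("`los_multipliers` must be named by unit id.")
    l_unit[names(los_multipliers)] <- los_multipliers
  }

  # severity: zero-truncated normal, integer scores
  lo <- stats::pnorm(0, config$saps3_location, config$saps3_scale)
  saps3 <- pmax(0, round(stats::qnorm(stats::runif(N, lo, 1),
                                      config$saps3_location,
                                      config$saps3_scale)))
  age <- pmax(16, round(stats::qnorm(stats::runif(N, stats::pnorm(16, 63, 20), 1),
                                     63, 20)))
  admission_type <- sample(c("medical", "scheduled surgery", "emergency surgery"),
                           N, replace = TRUE,
                           prob = c(0.683, 0.250, 0.067))

  # mortality: intercept-shift calibration on the realized severities and
  # unit multipliers, so the pooled simulated mortality hits the target
  logit <- config$coefficients$intercept +
    config$coefficients$slope * log(saps3 + config$coefficients$offset)
  mult <- m_unit[unit_id]
  shift_for <- function(target) {
    stats::uniroot(function(d)
      mean(pmin(stats::plogis(logit + d) * mult, 1)) - target,
      c(-15, 15), tol = 1e-10)$root
  }
  shift_icu <- shift_for(config$mortality_calibration)
  shift_hosp <- max(shift_for(config$hospital_mortality_calibration),
                    shift_icu)
  p_icu <- pmin(stats::plogis(logit + shift_icu) * mult, 1)
  p_hosp <- pmax(pmin(stats::plogis(logit + shift_hosp) * mult, 1), p_icu)
  u <- stats::runif(N)
  icu_death <- u < p_icu
  hospital_death <- u < p_hosp

  z <- (saps3 - config$saps3_location) / config$saps3_scale
  resid_sd <- sqrt(config$los_sdlog^2 - config$los_severity_coef^2)
  icu_los <- stats::rlnorm(N, config$los_meanlog +
                             config$los_severity_coef * z +
                             log(l_unit[unit_id]), resid_sd)
  post_icu <- ifelse(icu_death, 0, stats::rlnorm(N, log(4), 1.0))
  hospital_los <- icu_los + post_icu

  patients <- data.frame(
    patient_id = sprintf("P%07d", seq_len(N)),
    unit_id = unit_id,
    age = age,
    admission_type = admission_type,
    saps3 = as.integer(saps3),
    icu_los = icu_los,
    hospital_los = hospital_los,
    icu_death = icu_death,
    hospital_death = hospital_death,
    stringsAsFactors = FALSE)
  rownames(patients) <- NULL
  attr(patients, "coefficients_icu") <-
    shift_coefficients(config$coefficients, shift_icu, " [ICU-calibrated]")
  attr(patients, "coefficients_hospital") <-
    shift_coefficients(config$coefficients, shift_hosp, " [hospital-calibrated]")
  attr(patients, "unit_multipliers") <-
    data.frame(unit_id = units$unit_id, mortality_multiplier = as.numeric(m_unit),
               los_multiplier = as.numeric(l_unit), stringsAsFactors = FALSE)
  patients
}

#' Plant a known efficient frontier into a unit table
#'
#' Rewrites the DEA-relevant variables of a unit table (which must already
#' carry \code{smr} and \code{sru} columns) so that the units named in
#' \code{efficient_ids} form the exact efficient set of every built-in model:
#' planted units are placed on a common geometric ladder (mutually
#' non-dominated, all frontier vertices in both orientations), and every
#' other unit is strictly dominated by one planted unit — all model-scale
#' inputs at least \code{(1 + dominance_margin)} times larger, all
#' model-scale outputs at least that factor smaller. Deterministic: no random
#' draws.
#'
#' @param units Unit table containing the staffing ratio, bed, hour and
#'   occupancy columns plus \code{smr} and \code{sru}.
#' @param efficient_ids Non-empty subset of \code{units$unit_id} to plant as
#'   the efficient set.
#' @param dominance_margin Strictly positive dominance margin (e.g. 0.2).
#' @return The modified unit table (same rows and columns).
#' @export
plant_frontier <- function(units, efficient_ids, dominance_margin) {
  straight_inputs <- c("physicians_per_10_beds", "nurses_per_10_beds",
                       "nursing_techs_per_10_beds", "physios_per_10_beds",
                       "icu_beds", "physician_hours_week", "nurse_hours_week")
  need <- c("unit_id", straight_inputs, "occupancy", "smr", "sru")
  missing_cols <- setdiff(need, names(units))
  if (length(missing_cols))
    stop("`units` lacks column(s): ", paste(missing_cols, collapse = ", "),
         " (join the smr/sru performance columns before planting).")
  if (length(efficient_ids) == 0L) stop("`efficient_ids` must be non-empty.")
  if (!all(efficient_ids %in% units$unit_id))
    stop("`efficient_ids` must be a subset of units$unit_id.")
  if (!is.numeric(dominance_margin) || dominance_margin <= 0)
    stop("`dominance_margin` must be > 0.")
  c1 <- 1 + dominance_margin
  K <- length(efficient_ids)

  # base point: column medians (occupancy capped so the ladder stays <= 1)
  base_in <- vapply(units[straight_inputs], stats::median, numeric(1))
  base_occ <- min(stats::median(units$occupancy), 0.95)
  base_out <- c(smr = stats::median(units$smr), sru = stats::median(units$sru))

  planted_idx <- match(efficient_ids, units$unit_id)
  for (i in seq_len(K)) {
    f <- c1^(i - 1)
    units[planted_idx[i], straight_inputs] <- as.list(base_in * f)
    units$occupancy[planted_idx[i]] <- base_occ / f
    units$smr[planted_idx[i]] <- base_out["smr"] / f
    units$sru[planted_idx[i]] <- base_out["sru"] / f
  }
  other_idx <- setdiff(seq_len(nrow(units)), planted_idx)
  for (k in seq_along(other_idx)) {
    j <- other_idx[k]
    anchor <- 1L + (k - 1L) %% K          # planted unit that dominates j
    mstep <- 1L + (k - 1L) %/% K %% 3L    # 1..3 margin multiples for variety
    fa <- c1^(anchor - 1)
    fj <- fa * c1^mstep
    units[j, straight_inputs] <- as.list(base_in * fj)
    units$occupancy[j] <- base_occ / fj
    units$smr[j] <- base_out["smr"] * c1^mstep / fa
    units$sru[j] <- base_out["sru"] * c1^mstep / fa
  }
  units$bed_proportion <- units$icu_beds / units$hospital_beds
  units
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_units()] then [generate_patients()] and optionally writes
#' \code{units.csv}, \code{patients.csv} and a JSON manifest to a directory.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory (created if needed).
#' @inheritParams generate_patients
#' @return List with \code{units}, \code{patients}, \code{coefficients_icu},
#'   \code{coefficients_hospital} and the \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            mortality_multipliers = NULL,
                            los_multipliers = NULL) {
  units <- generate_units(config)
  patients <- generate_patients(units, config, mortality_multipliers,
                                los_multipliers)
  out <- list(units = units, patients = patients,
              coefficients_icu = attr(patients, "coefficients_icu"),
              coefficients_hospital = attr(patients, "coefficients_hospital"),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(units, file.path(out_dir, "units.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(patients, file.path(out_dir, "patients.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    manifest <- list(
      generator = "icudea::simulate_cohort",
      package_version = as.character(utils::packageVersion("icudea")),
      seed = config$seed, n_units = config$n_units,
      n_patients = nrow(patients),
      coefficients_icu = unclass(out$coefficients_icu)[1:3],
      coefficients_hospital = unclass(out$coefficients_hospital)[1:3])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
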