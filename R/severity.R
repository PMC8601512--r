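#' @title Severity-adjusted unit performance metrics (SMR and SRU)
#' @description Internal validation of a patient-level table.
#' @noRd
check_patients <- function(patients,
                           cols = c("unit_id", "saps3", "icu_los",
                                    "icu_death", "hospital_death")) {
  if (!is.data.frame(patients) || nrow(patients) == 0L)
    stop("`patients` must be a non-empty data frame.")
  missing_cols <- setdiff(cols, names(patients))
  if (length(missing_cols))
    stop("`patients` lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  invisible(patients)
}

outcome_column <- function(outcome = c("hospital", "icu")) {
  outcome <- match.arg(outcome)
  if (outcome == "hospital") "hospital_death" else "icu_death"
}

#' Standardized mortality ratio per unit
#'
#' Computes, for each ICU, observed deaths, expected deaths under the SAPS-3
#' risk equation, and their ratio (SMR). Expected deaths are the sum of
#' per-admission predicted probabilities. Units with zero expected deaths get
#' a missing SMR (never +/-Inf).
#'
#' The SAPS-3 equation predicts hospital mortality, so \code{outcome =
#' "hospital"} is the default; \code{"icu"} matches the convention of
#' reporting deaths occurring in the ICU and should be paired with an
#' ICU-calibrated coefficient set.
#'
#' @param patients Data frame with columns \code{unit_id}, \code{saps3},
#'   \code{icu_death}, \code{hospital_death} (one row per admission).
#' @param coefficients A [saps3_coefficients()] object.
#' @param outcome \code{"hospital"} (default) or \code{"icu"}: which death
#'   indicator counts as observed.
#'
#' @return Data frame with one row per unit: \code{unit_id},
#'   \code{n_admissions}, \code{observed_deaths}, \code{expected_deaths},
#'   \code{smr}.
#'
#' @seealso [compute_sru()], [unit_performance()]
#' @export
compute_smr <- function(patients, coefficients = saps3_coefficients(),
                        outcome = c("hospital", "icu")) {
  check_patients(patients, c("unit_id", "saps3", outcome_column(outcome)))
  col <- outcome_column(outcome)
  died <- as.logical(patients[[col]])
  if (anyNA(died)) stop("missing values in `", col, "`.")
  risk <- saps3_risk(patients$saps3, coefficients)
  unit <- factor(patients$unit_id, levels = unique(patients$unit_id))
  observed <- as.numeric(tapply(died, unit, sum))
  expected <- as.numeric(tapply(risk, unit, sum))
  n <- as.integer(tapply(died, unit, length))
  smr <- ifelse(expected > 0, observed / expected, NA_real_)
  if (any(expected == 0 & observed > 0))
    warning("unit(s) with observed deaths but zero expected deaths: SMR set to NA.")
  data.frame(unit_id = levels(unit), n_admissions = n,
             observed_deaths = observed, expected_deaths = expected,
             smr = smr, stringsAsFactors = FALSE)
}

#' Severity strata and survivor-based reference resource use
#'
#' Partitions the cohort's SAPS-3 range into quantile bands and computes, per
#' band, the reference resource use: total ICU length of stay of all cohort
#' patients in the band divided by the number of survivors in the band. Bands
#' without survivors are merged into the adjacent lower band (the lowest such
#' band merges upward), so every returned band has a finite reference value.
#'
#' @param patients Patient-level data frame (see [compute_smr()]); must also
#'   contain \code{icu_los}.
#' @param n_strata Number of quantile bands requested (default 10, deciles).
#' @param outcome Which death indicator defines a survivor (default
#'   \code{"hospital"}).
#'
#' @return Data frame of class \code{"severity_strata"}: columns \code{lower},
#'   \code{upper} (half-open band \code{[lower, upper)}, the last band closed
#'   above by +Inf), \code{n}, \code{n_survivors},
#'   \code{reference_use_per_survivor} (days per survivor).
#'
#' @export
build_severity_strata <- function(patients, n_strata = 10L,
                                  outcome = c("hospital", "icu")) {
  check_patients(patients)
  col <- outcome_column(outcome)
  n_strata <- as.integer(n_strata)
  if (n_strata < 1L) stop("`n_strata` must be >= 1.")
  survivor <- !as.logical(patients[[col]])
  if (!any(survivor))
    stop("no survivors in the cohort: SRU reference is undefined.")
  s <- as.numeric(patients$saps3)
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = n_strata + 1L),
                                   type = 7, names = FALSE))
  if (length(breaks) == 1L) breaks <- rep(breaks, 2L)  # constant severity
  # half-open bands [b_k, b_{k+1}), last band open above
  band <- findInterval(s, breaks[-c(1L, length(breaks))]) + 1L
  k <- length(breaks) - 1L
  los_band <- as.numeric(tapply(patients$icu_los, factor(band, levels = 1:k),
                                sum, default = 0))
  surv_band <- as.numeric(tapply(survivor, factor(band, levels = 1:k),
                                 sum, default = 0))
  n_band <- as.numeric(tapply(rep(1, length(s)), factor(band, levels = 1:k),
                              sum, default = 0))
  lower <- breaks[-length(breaks)]
  upper <- c(breaks[-1][-k], Inf)

  # merge zero-survivor bands downward (first band merges upward)
  i <- 1L
  while (i <= length(surv_band)) {
    if (surv_band[i] == 0 && length(surv_band) > 1L) {
      j <- if (i == 1L) 2L else i - 1L   # absorb into neighbour
      tgt <- min(i, j); src <- max(i, j)
      los_band[tgt] <- los_band[tgt] + los_band[src]
      surv_band[tgt] <- surv_band[tgt] + surv_band[src]
      n_band[tgt] <- n_band[tgt] + n_band[src]
      upper[tgt] <- upper[src]
      los_band <- los_band[-src]; surv_band <- surv_band[-src]
      n_band <- n_band[-src]; lower <- lower[-src]; upper <- upper[-src]
      i <- 1L  # restart: merging can create new zero bands only transiently
    } else i <- i + 1L
  }
  out <- data.frame(lower = lower, upper = upper, n = n_band,
                    n_survivors = surv_band,
                    reference_use_per_survivor = los_band / surv_band)
  class(out) <- c("severity_strata", "data.frame")
  attr(out, "outcome") <- match.arg(outcome)
  out
}

#' Standardized resource use per unit
#'
#' SRU is observed over expected resource use with ICU length of stay as the
#' resource surrogate. Observed use of a unit is the total ICU LOS over all
#' its admissions (survivors and decedents); expected use is the sum over
#' severity bands of the unit's survivor count times the cohort reference use
#' per survivor in that band. Units with no survivors have undefined SRU
#' (missing value, with a warning); the unit row is retained.
#'
#' @param patients Patient-level data frame.
#' @param strata A [build_severity_strata()] result computed on the same
#'   cohort.
#'
#' @return Data frame: \code{unit_id}, \code{n_admissions},
#'   \code{observed_resource_use}, \code{expected_resource_use}, \code{sru}.
#'
#' @export
compute_sru <- function(patients, strata) {
  check_patients(patients)
  if (!inherits(strata, "severity_strata"))
    stop("`strata` must come from build_severity_strata().")
  col <- outcome_column(attr(strata, "outcome"))
  survivor <- !as.logical(patients[[col]])
  band <- findInterval(as.numeric(patients$saps3), strata$lower)
  band[band < 1L] <- 1L   # scores below the cohort minimum fall in band 1
  unit <- factor(patients$unit_id, levels = unique(patients$unit_id))
  observed <- as.numeric(tapply(patients$icu_los, unit, sum))
  n <- as.integer(tapply(patients$icu_los, unit, length))
  # survivors per unit x band
  surv_tab <- table(unit[survivor], factor(band[survivor],
                                           levels = seq_len(nrow(strata))))
  expected <- as.numeric(surv_tab %*% strata$reference_use_per_survivor)
  # table() drops nothing: rows are in levels(unit) order
  sru <- ifelse(expected > 0, observed / expected, NA_real_)
  if (any(expected == 0))
    warning(sprintf("%d unit(s) without survivors: SRU undefined (NA).",
                    sum(expected == 0)))
  data.frame(unit_id = levels(unit), n_admissions = n,
             observed_resource_use = observed,
             expected_resource_use = expected,
             sru = sru, stringsAsFactors = FALSE)
}

#' Unit-level performance table (SMR and SRU combined)
#'
#' Convenience wrapper running [compute_smr()], [build_severity_strata()] and
#' [compute_sru()] on one cohort and joining the results into the unit
#' performance table consumed by the DEA models and the efficiency matrix.
#'
#' @inheritParams compute_smr
#' @inheritParams build_severity_strata
#' @return Data frame with columns \code{unit_id}, \code{n_admissions},
#'   \code{observed_deaths}, \code{expected_deaths}, \code{smr},
#'   \code{observed_resource_use}, \code{expected_resource_use}, \code{sru}.
#'   The strata used are attached as attribute \code{"strata"}.
#' @export
unit_performance <- function(patients, coefficients = saps3_coefficients(),
                             outcome = c("hospital", "icu"), n_strata = 10L) {
  outcome <- match.arg(outcome)
  smr <- compute_smr(patients, coefficients, outcome)
  strata <- build_severity_strata(patients, n_strata, outcome)
  sru <- compute_sru(patients, strata)
  out <- merge(smr, sru[, c("unit_id", "observed_resource_use",
                            "expected_resource_use", "sru")],
               by = "unit_id", sort = FALSE)
  out <- out[match(smr$unit_id, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strata") <- strata
  attr(out, "outcome") <- outcome
  out
}
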