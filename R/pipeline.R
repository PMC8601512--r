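#' Specification of a DEA benchmarking model
#'
#' A named bundle of input variables, output variables, orientation and
#' reciprocal-transform flags, validated at construction.
#'
#' @param name Model name ("A", "B", "C" or custom).
#' @param focus Free-text description of the model's perspective.
#' @param input_variables,output_variables Non-empty, disjoint character
#'   vectors of column names.
#' @param orientation \code{"input"} or \code{"output"}.
#' @param inverted_variables Subset of the input/output variables to enter
#'   as reciprocals (undesirable variables).
#' @return An object of class \code{"dea_model_spec"}.
#' @export
dea_model_spec <- function(name, focus, input_variables, output_variables,
                           orientation = c("input", "output"),
                           inverted_variables = character()) {
  orientation <- match.arg(orientation)
  if (!length(input_variables) || !length(output_variables))
    stop("input and output variable lists must be non-empty.")
  if (length(intersect(input_variables, output_variables)))
    stop("input and output variable lists must be disjoint.")
  unknown <- setdiff(inverted_variables,
                     c(input_variables, output_variables))
  if (length(unknown))
    stop("inverted variable(s) not in the model: ",
         paste(unknown, collapse = ", "))
  structure(list(name = as.character(name), focus = as.character(focus),
                 input_variables = input_variables,
                 output_variables = output_variables,
                 orientation = orientation,
                 inverted_variables = inverted_variables),
            class = "dea_model_spec")
}

#' @export
print.dea_model_spec <- function(x, ...) {
  cat(sprintf("DEA model %s (%s, %s-oriented)\n", x$name, x$focus,
              x$orientation))
  cat("  inputs: ", paste(x$input_variables, collapse = ", "), "\n")
  cat("  outputs:", paste(x$output_variables, collapse = ", "), "\n")
  if (length(x$inverted_variables))
    cat("  entered as reciprocals:",
        paste(x$inverted_variables, collapse = ", "), "\n")
  invisible(x)
}

#' The three built-in ICU benchmarking models
#'
#' Model A (staffing, input-oriented): the four per-10-bed staffing ratios as
#' inputs. Model B (structure, output-oriented): ICU beds and weekly
#' physician/nurse hours as inputs. Model C (capacity, input-oriented): bed
#' occupancy as the single input, entered as its reciprocal because higher
#' occupancy is the harder operating condition. All models use SMR and SRU as
#' outputs, entered as reciprocals (lower is better).
#'
#' @return Named list of three [dea_model_spec()] objects ("A", "B", "C").
#' @export
builtin_model_specs <- function() {
  list(
    A = dea_model_spec("A", "staffing",
                       input_variables = c("physicians_per_10_beds",
                                           "nurses_per_10_beds",
                                           "nursing_techs_per_10_beds",
                                           "physios_per_10_beds"),
                       output_variables = c("smr", "sru"),
                       orientation = "input",
                       inverted_variables = c("smr", "sru")),
    B = dea_model_spec("B", "structure",
                       input_variables = c("icu_beds", "physician_hours_week",
                                           "nurse_hours_week"),
                       output_variables = c("smr", "sru"),
                       orientation = "output",
                       inverted_variables = c("smr", "sru")),
    C = dea_model_spec("C", "capacity",
                       input_variables = "occupancy",
                       output_variables = c("smr", "sru"),
                       orientation = "input",
                       inverted_variables = c("smr", "sru", "occupancy")))
}

#' Run one benchmarking model on a unit table
#'
#' Joins the unit table with the performance table (SMR/SRU), drops units
#' with missing or non-positive values in any model variable (with a
#' warning), fits the VRS DEA model and assembles the per-unit report:
#' scores, efficient flags, peers, reference counts and original-scale
#' projection targets.
#'
#' @param spec A [dea_model_spec()].
#' @param units Unit-level table (organizational variables).
#' @param performance A [unit_performance()] table, or \code{NULL} when
#'   \code{units} already carries \code{smr}/\code{sru} columns.
#' @return An object of class \code{"dea_model_report"}: list with
#'   \code{spec}, the [dea()] \code{fit}, \code{scores} (data frame),
#'   \code{targets} (original scale), \code{data} (the merged rows used) and
#'   \code{excluded} unit ids.
#' @export
run_model <- function(spec, units, performance = NULL) {
  stopifnot(inherits(spec, "dea_model_spec"))
  dat <- if (is.null(performance)) units else
    merge(units[, setdiff(names(units), c("smr", "sru")), drop = FALSE],
          performance[, c("unit_id", intersect(c("smr", "sru"),
                                               names(performance)))],
          by = "unit_id", sort = FALSE)
  vars <- c(spec$input_variables, spec$output_variables)
  missing_cols <- setdiff(vars, names(dat))
  if (length(missing_cols))
    stop("model ", spec$name, " variable(s) absent from the data: ",
         paste(missing_cols, collapse = ", "))
  vals <- dat[, vars, drop = FALSE]
  usable <- rowSums(is.na(vals) | vals <= 0) == 0L
  if (any(!usable))
    warning(sprintf("model %s: excluding %d unit(s) with missing or non-positive variables: %s",
                    spec$name, sum(!usable),
                    paste(utils::head(dat$unit_id[!usable], 10L),
                          collapse = ", ")))
  dat <- dat[usable, , drop = FALSE]
  if (nrow(dat) < 2L)
    stop("model ", spec$name, ": fewer than 2 usable units.")
  X <- as.matrix(dat[, spec$input_variables, drop = FALSE])
  Y <- as.matrix(dat[, spec$output_variables, drop = FALSE])
  fit <- dea(X, Y, orientation = spec$orientation,
             dmu_ids = dat$unit_id,
             inverted_inputs = spec$input_variables %in% spec$inverted_variables,
             inverted_outputs = spec$output_variables %in% spec$inverted_variables)
  rc <- reference_counts(fit)
  scores <- data.frame(unit_id = fit$dmu_ids,
                       score = as.numeric(fit$scores),
                       efficient = as.logical(fit$efficient),
                       weakly_efficient = as.logical(fit$weakly_efficient),
                       reference_count = as.integer(rc),
                       stringsAsFactors = FALSE)
  structure(list(spec = spec, fit = fit, scores = scores,
                 targets = targets(fit, "original"),
                 data = dat,
                 excluded = units$unit_id[!units$unit_id %in% dat$unit_id]),
            class = "dea_model_report")
}

#' @export
print.dea_model_report <- function(x, ...) {
  cat(sprintf("Model %s (%s, %s-oriented): %d units, %d efficient\n",
              x$spec$name, x$spec$focus, x$spec$orientation,
              nrow(x$scores), sum(x$scores$efficient)))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

quantile_iqr <- function(v) {
  # linear-interpolation quantiles (type 7), the package-wide convention
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Compare efficient and non-efficient units variable by variable
#'
#' For each model, the median and interquartile range of every model variable
#' (original scale) within the efficient and the non-efficient group. An
#' empty group yields missing statistics.
#'
#' @param reports Named list of [run_model()] reports.
#' @return Data frame: \code{model}, \code{variable}, \code{group},
#'   \code{n}, \code{median}, \code{q1}, \code{q3}.
#' @export
efficient_group_comparison <- function(reports) {
  rows <- lapply(reports, function(rep) {
    vars <- c(rep$spec$input_variables, rep$spec$output_variables)
    eff <- rep$scores$efficient
    do.call(rbind, lapply(vars, function(v) {
      do.call(rbind, lapply(c(TRUE, FALSE), function(g) {
        vals <- rep$data[[v]][eff == g]
        q <- if (length(vals)) quantile_iqr(vals) else
          c(q1 = NA_real_, median = NA_real_, q3 = NA_real_)
        data.frame(model = rep$spec$name, variable = v,
                   group = if (g) "efficient" else "non_efficient",
                   n = length(vals), median = q[["median"]],
                   q1 = q[["q1"]], q3 = q[["q3"]],
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bed-proportion tercile assignment
#'
#' Fixed cutoffs reproduce the study's published terciles: low when the
#' proportion is <= the lower cutoff (4.70\%), high when >= the upper cutoff
#' (9.57\%), medium strictly in between. With \code{mode = "data"} the
#' cutoffs are recomputed as the data's own terciles (linear-interpolation
#' quantiles) under the same boundary rules.
#'
#' @param bed_proportion Numeric vector of ICU-to-hospital bed proportions.
#' @param mode \code{"fixed"} (default) or \code{"data"}.
#' @param cutoffs Length-2 numeric vector (low and high cutoff) used in
#'   fixed mode.
#' @return Character vector in \{"low", "medium", "high"\}.
#' @export
bed_proportion_tercile <- function(bed_proportion, mode = c("fixed", "data"),
                                   cutoffs = c(0.047, 0.0957)) {
  mode <- match.arg(mode)
  if (mode == "data")
    cutoffs <- stats::quantile(bed_proportion, c(1, 2) / 3, type = 7,
                               names = FALSE)
  ifelse(bed_proportion <= cutoffs[1L], "low",
         ifelse(bed_proportion >= cutoffs[2L], "high", "medium"))
}

#' Mean efficiency by organizational characteristic
#'
#' For each non-discretionary grouping variable — hospital administration,
#' hospital size, specialized ICU (type not mixed/medical) and
#' bed-proportion tercile — the per-category mean DEA score of every model,
#' mean SMR and SRU, unit count and count of efficient units.
#'
#' @param reports Named list of [run_model()] reports (names = model names).
#' @param units Unit-level table.
#' @param performance A [unit_performance()] table.
#' @param tercile_mode Passed to [bed_proportion_tercile()].
#' @return Data frame: \code{grouping_variable}, \code{category}, \code{n},
#'   \code{mean_smr}, \code{mean_sru}, then \code{mean_score_<model>} and
#'   \code{n_efficient_<model>} per model.
#' @export
group_efficiency_summary <- function(reports, units, performance,
                                     tercile_mode = c("fixed", "data")) {
  tercile_mode <- match.arg(tercile_mode)
  dat <- merge(units[, setdiff(names(units), c("smr", "sru")), drop = FALSE],
               performance[, c("unit_id", "smr", "sru")],
               by = "unit_id", sort = FALSE)
  groupings <- list(
    admin = dat$admin,
    hospital_size = if ("hospital_beds" %in% names(dat))
      hospital_size_category(dat$hospital_beds) else
        dat$hospital_size_category,
    specialized = ifelse(dat$icu_type %in% c("mixed", "medical"), "no", "yes"),
    bed_proportion_tercile = bed_proportion_tercile(dat$bed_proportion,
                                                    tercile_mode))
  known <- list(admin = c("public", "philanthropic", "for_profit"),
                hospital_size = c("small", "medium", "large"),
                specialized = c("yes", "no"),
                bed_proportion_tercile = c("low", "medium", "high"))
  model_names <- names(reports)
  rows <- lapply(names(groupings), function(gv) {
    g <- groupings[[gv]]
    bad <- setdiff(unique(g), known[[gv]])
    if (length(bad))
      stop(sprintf("unknown %s category '%s' (unit %s).", gv, bad[1L],
                   dat$unit_id[match(bad[1L], g)]))
    cats <- intersect(known[[gv]], unique(g))
    do.call(rbind, lapply(cats, function(cc) {
      in_c <- g == cc
      row <- data.frame(grouping_variable = gv, category = cc,
                        n = sum(in_c),
                        mean_smr = mean(dat$smr[in_c], na.rm = TRUE),
                        mean_sru = mean(dat$sru[in_c], na.rm = TRUE),
                        stringsAsFactors = FALSE)
      for (mn in model_names) {
        sc <- reports[[mn]]$scores
        idx <- match(dat$unit_id[in_c], sc$unit_id)
        row[[paste0("mean_score_", mn)]] <- mean(sc$score[idx], na.rm = TRUE)
        row[[paste0("n_efficient_", mn)]] <- sum(sc$efficient[idx],
                                                 na.rm = TRUE)
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Run the full benchmarking pipeline
#'
#' Wires the stages end to end: load (or simulate) the cohort, compute the
#' unit performance table (or accept a precomputed one), fit the requested
#' DEA models, classify the efficiency-matrix quadrants, and build the
#' quadrant, group and efficient-versus-non-efficient summaries. Optionally
#' writes every table as CSV plus a JSON run manifest.
#'
#' @param config A list (or path to a JSON file) with any of the fields:
#'   \code{patients} (CSV path), \code{units} (CSV path),
#'   \code{precomputed_performance} (CSV path with unit-level SMR/SRU,
#'   skipping the metrics stage), \code{simulate} (a [cohort_config()] or a
#'   list of its arguments), \code{models} (subset of \code{c("A","B","C")},
#'   default all), \code{outcome} ("hospital" or "icu"),
#'   \code{n_strata} (default 10), \code{tercile_mode} ("fixed" or "data"),
#'   \code{coefficients} (list with intercept/slope/offset), \code{seed}
#'   (overrides the simulation seed), \code{out_dir} (output directory).
#' @return An object of class \code{"icu_benchmark"}: list with
#'   \code{units}, \code{performance}, \code{reports}, \code{matrix},
#'   \code{quadrant_summary}, \code{group_summary},
#'   \code{efficient_comparison}, \code{scatter_data} and \code{manifest}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  models_wanted <- config$models %||% c("A", "B", "C")
  outcome <- config$outcome %||% "hospital"
  n_strata <- config$n_strata %||% 10L
  tercile_mode <- config$tercile_mode %||% "fixed"

  coefficients <- if (!is.null(config$coefficients))
    do.call(saps3_coefficients,
            config$coefficients[intersect(names(config$coefficients),
                                          c("intercept", "slope", "offset",
                                            "source_label"))])
  else saps3_coefficients()

  patients <- NULL
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    if (!inherits(sim_cfg, "cohort_config"))
      sim_cfg <- do.call(cohort_config, as.list(sim_cfg))
    if (!is.null(config$seed)) {
      args <- unclass(sim_cfg); args$seed <- as.integer(config$seed)
      sim_cfg <- do.call(cohort_config, args)
    }
    sim <- simulate_cohort(sim_cfg)
    units <- sim$units
    patients <- sim$patients
    # synthetic cohorts are scored against the matching calibrated equation
    if (is.null(config$coefficients))
      coefficients <- if (outcome == "icu") sim$coefficients_icu else
        sim$coefficients_hospital
  } else {
    if (is.null(config$units))
      stop("config must provide `units` (CSV path) or `simulate`.")
    units <- read_table_csv(config$units)
    if (!is.null(config$patients)) patients <- read_table_csv(config$patients)
  }

  if (!is.null(config$precomputed_performance)) {
    performance <- read_table_csv(config$precomputed_performance)
    if (!all(c("unit_id", "smr", "sru") %in% names(performance)))
      stop("precomputed performance table needs columns unit_id, smr, sru.")
  } else {
    if (is.null(patients))
      stop("either `patients` (or `simulate`) or `precomputed_performance` is required.")
    performance <- unit_performance(patients, coefficients,
                                    outcome = outcome, n_strata = n_strata)
  }

  specs <- builtin_model_specs()[models_wanted]
  if (anyNA(names(specs))) stop("unknown model name in `models`.")
  reports <- lapply(specs, run_model, units = units,
                    performance = performance)

  labels <- classify_quadrants(performance)
  fits <- lapply(reports, `[[`, "fit")
  quad_summary <- quadrant_dea_summary(labels, fits)
  group_summary <- group_efficiency_summary(reports, units, performance,
                                            tercile_mode)
  eff_comparison <- efficient_group_comparison(reports)
  scatter <- lapply(fits, function(f) {
    keep <- labels$unit_id %in% f$dmu_ids
    efficiency_scatter_data(labels[keep, , drop = FALSE], f)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("icudea")),
    models = names(specs), outcome = outcome, n_strata = n_strata,
    tercile_mode = tercile_mode,
    efficiency_tolerance = 1e-6,
    seed = config$seed %||% (if (!is.null(sim)) sim$config$seed else NA),
    n_units = nrow(units),
    n_patients = if (!is.null(patients)) nrow(patients) else NA,
    coefficients = list(intercept = coefficients$intercept,
                        slope = coefficients$slope,
                        offset = coefficients$offset,
                        source_label = coefficients$source_label),
    excluded_units = stats::setNames(lapply(reports, `[[`, "excluded"),
                                     names(reports)))

  bundle <- structure(list(units = units, performance = performance,
                           reports = reports, matrix = labels,
                           quadrant_summary = quad_summary,
                           group_summary = group_summary,
                           efficient_comparison = eff_comparison,
                           scatter_data = scatter,
                           manifest = manifest),
                      class = "icu_benchmark")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wcsv(bundle$performance, "unit_performance.csv")
  for (mn in names(bundle$reports)) {
    wcsv(bundle$reports[[mn]]$scores, sprintf("scores_%s.csv", mn))
    wcsv(bundle$reports[[mn]]$targets, sprintf("targets_%s.csv", mn))
    wcsv(bundle$scatter_data[[mn]], sprintf("fig1_data_%s.csv", mn))
  }
  wcsv(bundle$matrix, "efficiency_matrix.csv")
  wcsv(bundle$quadrant_summary, "quadrant_summary.csv")
  wcsv(bundle$group_summary, "group_summary.csv")
  wcsv(bundle$efficient_comparison, "efficient_group_comparison.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.icu_benchmark <- function(x, ...) {
  cat(sprintf("ICU benchmarking run: %d units, models %s\n",
              nrow(x$units), paste(names(x$reports), collapse = ", ")))
  for (mn in names(x$reports)) {
    sc <- x$reports[[mn]]$scores
    cat(sprintf("  model %s (%s-oriented): %d efficient of %d, mean score %.3f\n",
                mn, x$reports[[mn]]$spec$orientation, sum(sc$efficient),
                nrow(sc), mean(sc$score)))
  }
  tab <- table(x$matrix$quadrant)
  cat("Efficiency matrix:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
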