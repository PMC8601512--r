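#' Classify units into SMR x SRU efficiency-matrix quadrants
#'
#' The classical ICU efficiency matrix splits units at the cohort medians of
#' SMR and SRU: "most efficient" (low SMR, low SRU), "overachieving" (low
#' SMR, high SRU), "least efficient" (high SMR, high SRU) and
#' "underachieving" (high SMR, low SRU). The tie rule at the median is
#' configurable; by default a value equal to the median counts as "low".
#' Units lacking SMR or SRU are excluded from the matrix and reported in the
#' \code{"excluded"} attribute.
#'
#' @param performance A [unit_performance()] table (needs \code{unit_id},
#'   \code{smr}, \code{sru}).
#' @param tie \code{"le"} (default): low means value <= median; \code{"lt"}:
#'   low means value < median.
#' @return Data frame: \code{unit_id}, \code{smr}, \code{sru},
#'   \code{quadrant} (factor), \code{smr_median}, \code{sru_median};
#'   attribute \code{"excluded"} holds the ids of dropped units.
#' @export
classify_quadrants <- function(performance, tie = c("le", "lt")) {
  tie <- match.arg(tie)
  need <- c("unit_id", "smr", "sru")
  if (!all(need %in% names(performance)))
    stop("`performance` needs columns unit_id, smr, sru.")
  ok <- !is.na(performance$smr) & !is.na(performance$sru)
  excluded <- performance$unit_id[!ok]
  perf <- performance[ok, , drop = FALSE]
  if (nrow(perf) < 2L)
    stop("need at least 2 units with defined SMR and SRU.")
  smr_med <- stats::median(perf$smr)
  sru_med <- stats::median(perf$sru)
  low <- function(v, m) if (tie == "le") v <= m else v < m
  low_smr <- low(perf$smr, smr_med)
  low_sru <- low(perf$sru, sru_med)
  quadrant <- ifelse(low_smr & low_sru, "most_efficient",
              ifelse(low_smr & !low_sru, "overachieving",
              ifelse(!low_smr & !low_sru, "least_efficient",
                     "underachieving")))
  out <- data.frame(unit_id = perf$unit_id, smr = perf$smr, sru = perf$sru,
                    quadrant = factor(quadrant,
                                      levels = c("most_efficient",
                                                 "overachieving",
                                                 "least_efficient",
                                                 "underachieving")),
                    smr_median = smr_med, sru_median = sru_med,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Summarise DEA scores within efficiency-matrix quadrants
#'
#' Cross-tabulates quadrant membership against one or more fitted DEA models:
#' per quadrant and model, the number of units, mean and standard deviation
#' of the efficiency scores, and the count of DEA-efficient units. Empty
#' quadrants are kept with \code{n = 0} and missing statistics.
#'
#' @param labels A [classify_quadrants()] table.
#' @param results A single [dea()] fit or a named list of fits (one per
#'   model).
#' @return Data frame: \code{model}, \code{quadrant}, \code{n},
#'   \code{mean_score}, \code{sd_score}, \code{n_efficient}.
#' @export
quadrant_dea_summary <- function(labels, results) {
  if (inherits(results, "dea")) results <- list(model = results)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("model", seq_along(results))
  quads <- levels(labels$quadrant)
  rows <- lapply(names(results), function(mn) {
    fit <- results[[mn]]
    idx <- match(labels$unit_id, fit$dmu_ids)
    if (anyNA(idx))
      stop("DEA fit '", mn, "' is missing unit(s) present in the matrix.")
    sc <- fit$scores[idx]
    eff <- fit$efficient[idx]
    do.call(rbind, lapply(quads, function(q) {
      in_q <- labels$quadrant == q
      n <- sum(in_q)
      data.frame(model = mn, quadrant = q, n = n,
                 mean_score = if (n) mean(sc[in_q]) else NA_real_,
                 sd_score = if (n > 1L) stats::sd(sc[in_q]) else NA_real_,
                 n_efficient = sum(eff[in_q]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scatter-table of SMR, SRU and DEA results
#'
#' The underlying table of the SMR-versus-SRU scatter display: per unit, the
#' two metrics, the quadrant, the DEA score and efficient flag, and the
#' number of times the unit is a reference to others.
#'
#' @param labels A [classify_quadrants()] table.
#' @param fit A [dea()] fit on the same units.
#' @return Data frame: \code{unit_id}, \code{smr}, \code{sru},
#'   \code{quadrant}, \code{score}, \code{efficient},
#'   \code{reference_count}.
#' @export
efficiency_scatter_data <- function(labels, fit) {
  stopifnot(inherits(fit, "dea"))
  idx <- match(labels$unit_id, fit$dmu_ids)
  if (anyNA(idx)) stop("DEA fit is missing unit(s) present in the matrix.")
  rc <- reference_counts(fit)
  data.frame(unit_id = labels$unit_id, smr = labels$smr, sru = labels$sru,
             quadrant = labels$quadrant,
             score = as.numeric(fit$scores[idx]),
             efficient = as.logical(fit$efficient[idx]),
             reference_count = as.integer(rc[idx]),
             stringsAsFactors = FALSE)
}
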