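#' SAPS-3 logistic mortality equation coefficients
#'
#' Parameters of the logistic hospital-mortality risk equation associated
#' with the Simplified Acute Physiology Score 3 (SAPS-3):
#' \deqn{\mathrm{logit}(p) = \alpha + \beta \, \ln(\mathrm{SAPS3} + \gamma)}
#' The defaults are the published global equation (Moreno et al., 2005,
#' Intensive Care Medicine 31:1345-1355):
#' intercept -32.6659, slope 7.3068, offset 20.5958. Regional customisations
#' of the equation can be supplied by overriding the three parameters.
#'
#' @param intercept Real; additive constant \eqn{\alpha} on the logit scale.
#' @param slope Real > 0; coefficient \eqn{\beta} of \eqn{\ln(score + offset)}.
#'   Must be positive so that risk increases with severity.
#' @param offset Real; shift \eqn{\gamma} applied to the score before the
#'   logarithm. \code{score + offset} must be positive for every score the
#'   equation is evaluated at.
#' @param source_label Character; provenance tag stored with the coefficients.
#'
#' @return An object of class \code{"saps3_coefficients"}: a list with the
#'   four fields above.
#'
#' @examples
#' cf <- saps3_coefficients()
#' saps3_risk(44, cf)
#' @export
saps3_coefficients <- function(intercept = -32.6659,
                               slope = 7.3068,
                               offset = 20.5958,
                               source_label = "SAPS-3 global equation (Moreno 2005)") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  if (slope <= 0)
    stop("`slope` must be > 0: mortality risk must increase with the score.")
  structure(list(intercept = intercept, slope = slope, offset = offset,
                 source_label = as.character(source_label)[1L]),
            class = "saps3_coefficients")
}

#' @export
print.saps3_coefficients <- function(x, ...) {
  cat("SAPS-3 risk equation:", x$source_label, "\n")
  cat(sprintf("  logit(p) = %.4f + %.4f * ln(score + %.4f)\n",
              x$intercept, x$slope, x$offset))
  invisible(x)
}

#' Predicted mortality probability from a SAPS-3 score
#'
#' Evaluates the logistic risk equation
#' \eqn{p = \mathrm{expit}(\alpha + \beta \ln(s + \gamma))} for one or more
#' SAPS-3 scores. The result is strictly increasing in the score.
#'
#' @param saps3 Numeric vector of SAPS-3 scores (points, >= 0 in practice).
#' @param coefficients A [saps3_coefficients()] object.
#'
#' @return Numeric vector of probabilities in (0, 1).
#'
#' @examples
#' saps3_risk(c(34, 44, 54))
#' @export
saps3_risk <- function(saps3, coefficients = saps3_coefficients()) {
  if (!inherits(coefficients, "saps3_coefficients"))
    stop("`coefficients` must be a saps3_coefficients object.")
  saps3 <- as.numeric(saps3)
  if (anyNA(saps3)) stop("`saps3` contains missing values.")
  shifted <- saps3 + coefficients$offset
  if (any(shifted <= 0))
    stop(sprintf("saps3 + offset must be > 0; violated for score(s) %s.",
                 paste(utils::head(saps3[shifted <= 0], 5L), collapse = ", ")))
  stats::plogis(coefficients$intercept + coefficients$slope * log(shifted))
}

# Intercept-shifted copy of a coefficient set; used by the cohort generator
# to calibrate pooled mortality without changing the equation's shape.
shift_coefficients <- function(coefficients, shift, label_suffix = "") {
  saps3_coefficients(intercept = coefficients$intercept + shift,
                     slope = coefficients$slope,
                     offset = coefficients$offset,
                     source_label = paste0(coefficients$source_label,
                                           label_suffix))
}
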