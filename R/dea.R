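#' Reciprocal transform for undesirable DEA variables
#'
#' DEA assumes that larger outputs and smaller inputs are better. Undesirable
#' variables — outputs where lower is better (SMR, SRU) or inputs where higher
#' is better (bed occupancy) — are entered on the reciprocal scale
#' \code{1/x}. The transform is an involution: applying it twice returns the
#' original values.
#'
#' @param values Strictly positive numeric vector.
#' @param flag Logical; if \code{TRUE} the reciprocal is returned, otherwise
#'   the values are returned unchanged.
#' @param label Variable name used in error messages.
#' @return Numeric vector of the same length.
#' @examples
#' invert_variables(c(0.5, 2), TRUE)
#' @export
invert_variables <- function(values, flag, label = "variable") {
  values <- as.numeric(values)
  if (anyNA(values) || any(values <= 0)) {
    bad <- which(is.na(values) | values <= 0)
    stop(sprintf("%s has non-positive or missing value(s) at position(s) %s; DEA variables must be > 0.",
                 label, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (isTRUE(flag)) 1 / values else values
}

check_dea_data <- function(X, Y, dmu_ids) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y))
    stop("X and Y must have one row per DMU (nrow mismatch).")
  n <- nrow(X)
  if (n < 1L) stop("at least one DMU is required.")
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y)))
    stop("X and Y must be finite and free of missing values.")
  if (any(X <= 0) || any(Y <= 0)) {
    bad <- unique(c(dmu_ids[rowSums(X <= 0) > 0], dmu_ids[rowSums(Y <= 0) > 0]))
    stop("non-positive value(s) in DMU(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ". DEA requires strictly positive data; exclude or correct these units.")
  }
  if (anyDuplicated(dmu_ids)) stop("duplicate DMU identifiers.")
  list(X = X, Y = Y)
}

# Solve the VRS envelopment problem for DMU o: phase 1 radial score, phase 2
# slack maximization at the fixed radial score. X, Y are n x m and n x s
# (rows = DMUs), model scale (already inverted where applicable).
solve_dea_dmu <- function(X, Y, o, orientation) {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  x0 <- X[o, ]; y0 <- Y[o, ]
  if (orientation == "input") {
    # min theta : X'lambda <= theta x0, Y'lambda >= y0, sum lambda = 1
    p1 <- solve_lp(objective = c(rep(0, n), 1),
                   A_le = cbind(t(X), -x0), b_le = rep(0, m),
                   A_ge = cbind(t(Y), 0),  b_ge = y0,
                   A_eq = matrix(c(rep(1, n), 0), 1L), b_eq = 1,
                   maximize = FALSE)
    score <- p1$value
    relax <- function(f) f * score  # radial input bound theta* x0
    rhs_in <- score * x0
    rhs_out <- y0
  } else {
    # max phi : X'lambda <= x0, Y'lambda >= phi y0, sum lambda = 1
    p1 <- solve_lp(objective = c(rep(0, n), 1),
                   A_le = cbind(t(X), 0),   b_le = x0,
                   A_ge = cbind(t(Y), -y0), b_ge = rep(0, s),
                   A_eq = matrix(c(rep(1, n), 0), 1L), b_eq = 1,
                   maximize = TRUE)
    score <- p1$value
    rhs_in <- x0
    rhs_out <- score * y0
  }
  # Phase 2: max total slack at fixed radial score.
  #   X'lambda + s_minus = rhs_in ; Y'lambda - s_plus = rhs_out ; sum lambda = 1
  nv <- n + m + s
  A_eq <- rbind(cbind(t(X), diag(m), matrix(0, m, s)),
                cbind(t(Y), matrix(0, s, m), -diag(s)),
                c(rep(1, n), rep(0, m + s)))
  obj <- c(rep(0, n), rep(1, m + s))
  p2 <- tryCatch(
    solve_lp(objective = obj, A_eq = A_eq, b_eq = c(rhs_in, rhs_out, 1),
             maximize = TRUE),
    error = function(e) NULL)
  if (is.null(p2)) {
    # floating-point infeasibility at the exact radial bound: nudge the bound
    # by 1e-9 in the relaxing direction and retry once
    bump <- 1e-9 * max(1, abs(score))
    rhs_in2 <- if (orientation == "input") (score + bump) * x0 else rhs_in
    rhs_out2 <- if (orientation == "output") (score - bump) * y0 else rhs_out
    p2 <- solve_lp(objective = obj, A_eq = A_eq,
                   b_eq = c(rhs_in2, rhs_out2, 1), maximize = TRUE)
  }
  sol <- p2$solution
  lambda <- sol[seq_len(n)]
  s_minus <- sol[n + seq_len(m)]
  s_plus <- sol[n + m + seq_len(s)]
  list(score = score, lambda = lambda,
       input_slacks = s_minus, output_slacks = s_plus)
}

#' Variable-returns-to-scale (BCC) data envelopment analysis
#'
#' Fits the VRS envelopment model to a set of decision-making units (DMUs),
#' solving one linear program per unit (plus a second, slack-maximizing phase
#' at the optimal radial score). In input orientation the score
#' \eqn{\theta \in (0, 1]} is the largest proportional input contraction
#' feasible at the unit's output level; in output orientation the score
#' \eqn{\varphi \in [1, \infty)} is the largest proportional output expansion
#' feasible at its input level. A unit is efficient when its radial score
#' equals 1 (within \code{tol}); weakly efficient units additionally carry
#' nonzero phase-2 slacks.
#'
#' Undesirable variables (lower-is-better outputs such as SMR and SRU, or
#' higher-is-better inputs such as bed occupancy) are declared via
#' \code{inverted_inputs}/\code{inverted_outputs} and are entered into the
#' model on the reciprocal scale; projection targets are reported on both
#' scales.
#'
#' @param X Numeric matrix or data frame of inputs, one row per DMU, strictly
#'   positive, on the original scale.
#' @param Y Numeric matrix or data frame of outputs, one row per DMU,
#'   strictly positive, on the original scale.
#' @param orientation \code{"input"} or \code{"output"}.
#' @param dmu_ids Character vector of unique DMU identifiers; defaults to the
#'   row names of \code{X} or \code{"DMU1"...}.
#' @param inverted_inputs,inverted_outputs Logical vectors (one flag per
#'   column of \code{X}/\code{Y}) marking variables to enter as reciprocals.
#' @param tol Efficiency tolerance: a unit is efficient when
#'   \code{|score - 1| <= tol} (default \code{1e-6}).
#' @param ... Passed on from the formula method; unused otherwise.
#'
#' @return An object of class \code{"dea"}: a list with elements
#'   \code{dmu_ids}, \code{orientation}, \code{scores}, \code{lambda}
#'   (n x n peer-weight matrix, rows = evaluated DMU), \code{input_slacks},
#'   \code{output_slacks}, \code{targets_model} and \code{targets_original}
#'   (each a list with \code{inputs} and \code{outputs} matrices),
#'   \code{efficient}, \code{weakly_efficient}, the model-scale data
#'   \code{X}, \code{Y}, the original-scale data \code{X_orig},
#'   \code{Y_orig}, the inversion flags and \code{tol}.
#'
#' @examples
#' X <- matrix(c(2, 4, 3), ncol = 1, dimnames = list(c("A", "B", "C"), "x"))
#' Y <- matrix(c(2, 4, 2), ncol = 1, dimnames = list(NULL, "y"))
#' fit <- dea(X, Y, orientation = "input")
#' coef(fit)            # C scores 2/3 with peer A
#' summary(fit)
#' @seealso [peers()], [targets()], [reference_counts()], [predict.dea()]
#' @export
dea <- function(X, ...) UseMethod("dea")

#' @rdname dea
#' @export
dea.default <- function(X, Y, orientation = c("input", "output"),
                        dmu_ids = NULL,
                        inverted_inputs = NULL, inverted_outputs = NULL,
                        tol = 1e-6, ...) {
  orientation <- match.arg(orientation)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(dmu_ids))
    dmu_ids <- if (!is.null(rownames(X))) rownames(X) else
      paste0("DMU", seq_len(nrow(X)))
  dmu_ids <- as.character(dmu_ids)
  if (length(dmu_ids) != nrow(X)) stop("`dmu_ids` length must equal nrow(X).")
  m <- ncol(X); s <- ncol(Y)
  if (m < 1L || s < 1L) stop("need at least one input and one output.")
  if (is.null(inverted_inputs)) inverted_inputs <- rep(FALSE, m)
  if (is.null(inverted_outputs)) inverted_outputs <- rep(FALSE, s)
  stopifnot(length(inverted_inputs) == m, length(inverted_outputs) == s)
  input_labels <- colnames(X) %||% paste0("input", seq_len(m))
  output_labels <- colnames(Y) %||% paste0("output", seq_len(s))

  chk <- check_dea_data(X, Y, dmu_ids)
  X_orig <- chk$X; Y_orig <- chk$Y
  Xm <- X_orig; Ym <- Y_orig
  for (i in seq_len(m)) Xm[, i] <- invert_variables(X_orig[, i],
                                                    inverted_inputs[i],
                                                    input_labels[i])
  for (r in seq_len(s)) Ym[, r] <- invert_variables(Y_orig[, r],
                                                    inverted_outputs[r],
                                                    output_labels[r])
  n <- nrow(Xm)
  scores <- numeric(n)
  lambda <- matrix(0, n, n, dimnames = list(dmu_ids, dmu_ids))
  s_in <- matrix(0, n, m, dimnames = list(dmu_ids, input_labels))
  s_out <- matrix(0, n, s, dimnames = list(dmu_ids, output_labels))
  for (o in seq_len(n)) {
    res <- tryCatch(solve_dea_dmu(Xm, Ym, o, orientation),
                    error = function(e)
                      stop(sprintf("DEA solve failed for DMU '%s': %s",
                                   dmu_ids[o], conditionMessage(e)),
                           call. = FALSE))
    scores[o] <- res$score
    lambda[o, ] <- res$lambda
    s_in[o, ] <- res$input_slacks
    s_out[o, ] <- res$output_slacks
  }
  # targets on the model scale are the peer-weighted averages
  t_in <- lambda %*% Xm
  t_out <- lambda %*% Ym
  dimnames(t_in) <- list(dmu_ids, input_labels)
  dimnames(t_out) <- list(dmu_ids, output_labels)
  t_in_orig <- t_in; t_out_orig <- t_out
  for (i in seq_len(m)) if (inverted_inputs[i]) t_in_orig[, i] <- 1 / t_in[, i]
  for (r in seq_len(s)) if (inverted_outputs[r]) t_out_orig[, r] <- 1 / t_out[, r]

  slack_eps <- 1e-6
  efficient <- abs(scores - 1) <= tol
  weakly <- efficient & (rowSums(s_in > slack_eps) + rowSums(s_out > slack_eps) > 0)

  structure(list(dmu_ids = dmu_ids, orientation = orientation,
                 scores = stats::setNames(scores, dmu_ids),
                 lambda = lambda,
                 input_slacks = s_in, output_slacks = s_out,
                 targets_model = list(inputs = t_in, outputs = t_out),
                 targets_original = list(inputs = t_in_orig,
                                         outputs = t_out_orig),
                 efficient = stats::setNames(efficient, dmu_ids),
                 weakly_efficient = stats::setNames(weakly, dmu_ids),
                 X = Xm, Y = Ym, X_orig = X_orig, Y_orig = Y_orig,
                 input_labels = input_labels, output_labels = output_labels,
                 inverted_inputs = inverted_inputs,
                 inverted_outputs = inverted_outputs,
                 tol = tol, call = match.call()),
            class = "dea")
}

#' @rdname dea
#' @param formula For the formula method: outputs on the left-hand side,
#'   inputs on the right, e.g. \code{cbind(smr, sru) ~ occupancy}.
#' @param data Data frame holding the formula variables; row names (or a
#'   \code{unit_id} column) supply the DMU identifiers.
#' @export
dea.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  Y <- as.matrix(stats::model.response(mf))
  if (is.null(dim(Y)) || ncol(Y) < 1L) Y <- matrix(Y, ncol = 1L)
  if (is.null(colnames(Y)))
    colnames(Y) <- deparse(formula[[2L]])
  terms_x <- stats::delete.response(stats::terms(formula, data = data))
  X <- as.matrix(mf[, attr(terms_x, "term.labels"), drop = FALSE])
  ids <- if ("unit_id" %in% names(data)) as.character(data$unit_id) else
    rownames(data)
  dea.default(X, Y, dmu_ids = ids, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dea <- function(x, ...) {
  n <- length(x$dmu_ids)
  cat(sprintf("VRS (BCC) DEA, %s-oriented: %d DMUs, %d input(s), %d output(s)\n",
              x$orientation, n, ncol(x$X), ncol(x$Y)))
  cat(sprintf("Efficient: %d of %d (%d weakly)\n",
              sum(x$efficient), n, sum(x$weakly_efficient)))
  cat("Scores:\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' @export
summary.dea <- function(object, ...) {
  out <- list(orientation = object$orientation,
              n = length(object$dmu_ids),
              n_efficient = sum(object$efficient),
              n_weakly = sum(object$weakly_efficient),
              score_summary = summary(object$scores),
              reference_counts = reference_counts(object),
              efficient_ids = object$dmu_ids[object$efficient])
  class(out) <- "summary.dea"
  out
}

#' @export
print.summary.dea <- function(x, ...) {
  cat(sprintf("VRS DEA (%s-oriented), %d DMUs\n", x$orientation, x$n))
  cat(sprintf("Efficient units: %d (of which weakly efficient: %d)\n",
              x$n_efficient, x$n_weakly))
  cat("Score distribution:\n"); print(x$score_summary)
  rc <- x$reference_counts[x$reference_counts > 0]
  if (length(rc)) {
    cat("Reference counts (times an efficient unit anchors another):\n")
    print(sort(rc, decreasing = TRUE))
  }
  invisible(x)
}

#' @export
coef.dea <- function(object, ...) object$scores

#' Efficiency scores of a fitted DEA model
#' @param object A [dea()] fit.
#' @param ... Unused.
#' @return Named numeric vector of radial scores.
#' @export
efficiencies <- function(object, ...) UseMethod("efficiencies")

#' @export
efficiencies.dea <- function(object, ...) object$scores

#' @export
residuals.dea <- function(object, ...) {
  # radial inefficiency: distance of the score from the frontier value 1
  if (object$orientation == "input") 1 - object$scores else object$scores - 1
}

#' Peer (reference) sets of a fitted DEA model
#'
#' @param object A [dea()] fit.
#' @param threshold Peer weights below this value are treated as zero
#'   (default \code{1e-7}).
#' @return Named list: for each DMU, the named vector of positive peer
#'   weights (lambdas) in its optimal solution.
#' @export
peers <- function(object, threshold = 1e-7) {
  stopifnot(inherits(object, "dea"))
  out <- lapply(seq_along(object$dmu_ids), function(o) {
    w <- object$lambda[o, ]
    w[w > threshold]
  })
  stats::setNames(out, object$dmu_ids)
}

#' Frontier projection targets
#'
#' Targets are the peer-weighted combinations \eqn{\sum_j \lambda_j x_j},
#' \eqn{\sum_j \lambda_j y_j}: the point on the frontier a non-efficient unit
#' should move to. For variables entered as reciprocals the original-scale
#' target is the reciprocal of the model-scale target.
#'
#' @param object A [dea()] fit.
#' @param scale \code{"original"} (default) or \code{"model"}.
#' @return Data frame: \code{dmu_id}, one column per input and output.
#' @export
targets <- function(object, scale = c("original", "model")) {
  stopifnot(inherits(object, "dea"))
  scale <- match.arg(scale)
  t <- if (scale == "original") object$targets_original else
    object$targets_model
  data.frame(dmu_id = object$dmu_ids, t$inputs, t$outputs,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reference counts of efficient units
#'
#' Counts, for each unit, how many other units use it as a peer (positive
#' lambda) in their optimal solutions. Self-references are excluded, so in a
#' dataset where every unit is efficient all counts are zero.
#'
#' @param object A [dea()] fit (or the `lambda` matrix of one).
#' @param threshold Weights below this value do not count (default 1e-7).
#' @return Named integer vector, one entry per DMU.
#' @export
reference_counts <- function(object, threshold = 1e-7) {
  lambda <- if (inherits(object, "dea")) object$lambda else as.matrix(object)
  pos <- lambda > threshold
  diag(pos) <- FALSE
  stats::setNames(as.integer(colSums(pos)), colnames(lambda))
}

#' Score new units against a fitted frontier
#'
#' Evaluates additional DMUs relative to the frontier spanned by the units
#' the model was fitted on (the new units do not reshape the frontier).
#' Inputs and outputs are supplied on the original scale; the fit's
#' reciprocal-transform flags are applied automatically.
#'
#' @param object A [dea()] fit.
#' @param newX,newY Matrices (or data frames) of inputs and outputs for the
#'   new units, columns matching the fitted model.
#' @param dmu_ids Optional identifiers for the new units.
#' @param ... Unused.
#' @return Data frame: \code{dmu_id}, \code{score}, \code{efficient}.
#' @export
predict.dea <- function(object, newX, newY, dmu_ids = NULL, ...) {
  newX <- as.matrix(newX); newY <- as.matrix(newY)
  if (ncol(newX) != ncol(object$X) || ncol(newY) != ncol(object$Y))
    stop("newX/newY must match the fitted model's variables.")
  if (is.null(dmu_ids))
    dmu_ids <- rownames(newX) %||% paste0("new", seq_len(nrow(newX)))
  k <- nrow(newX)
  Xm <- newX; Ym <- newY
  for (i in seq_len(ncol(newX)))
    Xm[, i] <- invert_variables(newX[, i], object$inverted_inputs[i],
                                object$input_labels[i])
  for (r in seq_len(ncol(newY)))
    Ym[, r] <- invert_variables(newY[, r], object$inverted_outputs[r],
                                object$output_labels[r])
  n <- nrow(object$X)
  scores <- numeric(k)
  for (o in seq_len(k)) {
    # reference set: fitted DMUs plus the evaluated unit itself (standard
    # envelopment feasibility: the self-solution keeps the LP feasible)
    Xa <- rbind(object$X, Xm[o, , drop = FALSE])
    Ya <- rbind(object$Y, Ym[o, , drop = FALSE])
    scores[o] <- solve_dea_dmu(Xa, Ya, n + 1L, object$orientation)$score
  }
  data.frame(dmu_id = dmu_ids, score = scores,
             efficient = abs(scores - 1) <= object$tol,
             stringsAsFactors = FALSE)
}

#' Plot method for DEA fits
#'
#' Draws the sorted efficiency scores with efficient units highlighted; a
#' quick visual of how far the cohort sits from the frontier.
#'
#' @param x A [dea()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dea <- function(x, ...) {
  ord <- order(x$scores)
  cols <- ifelse(x$efficient[ord], "steelblue", "grey40")
  graphics::plot(seq_along(x$scores), x$scores[ord], pch = 19, col = cols,
                 xlab = "units (sorted)", ylab = paste0("efficiency score (",
                 if (x$orientation == "input") "theta" else "phi", ")"), ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
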