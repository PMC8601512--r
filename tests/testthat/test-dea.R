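# Core VRS envelopment solver: worked geometry, oracle equivalence and the
# standard DEA invariants.

worked_X <- matrix(c(2, 4, 3), ncol = 1, dimnames = list(c("A", "B", "C"), "x"))
worked_Y <- matrix(c(2, 4, 2), ncol = 1, dimnames = list(NULL, "y"))

test_that("worked 3-DMU instance matches the closed-form frontier", {
  fin <- dea(worked_X, worked_Y, orientation = "input")
  expect_equal(unname(coef(fin)), c(1, 1, 2/3), tolerance = 1e-6)
  expect_equal(names(which(peers(fin)$C > 1e-7)), "A")
  expect_true(all(fin$efficient[c("A", "B")]))
  expect_false(fin$efficient["C"])

  fout <- dea(worked_X, worked_Y, orientation = "output")
  expect_equal(unname(coef(fout)), c(1, 1, 1.5), tolerance = 1e-6)

  rc <- reference_counts(fin)
  expect_equal(unname(rc[c("A", "B")]), c(1L, 0L))
})

test_that("degenerate and symmetric instances behave as geometry dictates", {
  # single DMU: self-reference, score 1, zero slacks
  f1 <- dea(matrix(3, 1, 1), matrix(2, 1, 1), orientation = "input",
            dmu_ids = "solo")
  expect_equal(unname(f1$scores), 1, tolerance = 1e-9)
  expect_equal(unname(f1$lambda[1, 1]), 1, tolerance = 1e-7)
  expect_equal(sum(f1$input_slacks) + sum(f1$output_slacks), 0,
               tolerance = 1e-7)
  expect_equal(unname(dea(matrix(3, 1, 1), matrix(2, 1, 1),
                          orientation = "output")$scores), 1,
               tolerance = 1e-9)

  # identical DMUs are all efficient by symmetry
  Xi <- matrix(rep(c(2, 3), each = 4), 4, 2)
  Yi <- matrix(rep(1.5, 4), 4, 1)
  expect_true(all(abs(dea(Xi, Yi, "input")$scores - 1) < 1e-7))
  expect_true(all(abs(dea(Xi, Yi, "output")$scores - 1) < 1e-7))
})

test_that("scores match the vertex-enumeration oracle on random instances", {
  set.seed(101)
  for (k in 1:40) {
    n <- sample(2:5, 1)
    m <- sample(1:2, 1)
    s <- sample.int(3 - m, 1)
    inst <- random_dea_instance(n, m, s)
    orient <- if (k %% 2) "input" else "output"
    fit <- dea(inst$X, inst$Y, orientation = orient)
    for (o in seq_len(n)) {
      expect_equal(unname(fit$scores[o]),
                   dea_oracle(inst$X, inst$Y, o, orient)$score,
                   tolerance = 1e-5,
                   label = sprintf("instance %d DMU %d (%s)", k, o, orient))
    }
  }
})

test_that("radial scores are units-invariant and respect their bounds", {
  set.seed(202)
  for (k in 1:10) {
    inst <- random_dea_instance(5, 2, 1)
    for (orient in c("input", "output")) {
      fit <- dea(inst$X, inst$Y, orientation = orient)
      if (orient == "input") {
        expect_true(all(fit$scores > 0 & fit$scores <= 1 + 1e-9))
      } else {
        expect_true(all(fit$scores >= 1 - 1e-9))
      }
      # convexity: peer weights sum to one at every optimum
      expect_true(all(abs(rowSums(fit$lambda) - 1) < 1e-7))
      # rescale one input and one output column by positive constants
      X2 <- inst$X; X2[, 1] <- X2[, 1] * 37.5
      Y2 <- inst$Y * 0.004
      fit2 <- dea(X2, Y2, orientation = orient)
      expect_equal(unname(fit$scores), unname(fit2$scores),
                   tolerance = 1e-7)
    }
  }
})

test_that("a strictly dominated DMU is never efficient; a strict input minimizer always is", {
  set.seed(303)
  for (k in 1:10) {
    inst <- random_dea_instance(4, 2, 1)
    # append a DMU strictly dominated by DMU 1
    X <- rbind(inst$X, inst$X[1, ] * 1.3)
    Y <- rbind(inst$Y, inst$Y[1, , drop = FALSE] * 0.7)
    for (orient in c("input", "output")) {
      fit <- dea(X, Y, orientation = orient)
      expect_false(fit$efficient[5])
    }
    # a DMU holding the strict minimum of some input is input-efficient
    # under VRS (no convex combination can undercut its minimal input)
    imin <- which.min(inst$X[, 1])
    expect_true(dea(inst$X, inst$Y, "input")$efficient[imin])
  }
})

test_that("appending a DMU never increases an input-oriented score", {
  set.seed(404)
  for (k in 1:8) {
    inst <- random_dea_instance(4, 1, 2)
    base <- dea(inst$X, inst$Y, "input")$scores
    Xa <- rbind(inst$X, matrix(stats::runif(1, 0.5, 5), 1, 1))
    Ya <- rbind(inst$Y, matrix(stats::runif(2, 0.5, 5), 1, 2))
    grown <- dea(Xa, Ya, "input")$scores
    expect_true(all(grown[1:4] <= base + 1e-7))
  }
})

test_that("frontier membership with zero slacks is orientation-free", {
  set.seed(505)
  for (k in 1:8) {
    inst <- random_dea_instance(5, 2, 1)
    fin <- dea(inst$X, inst$Y, "input")
    strong <- fin$efficient & !fin$weakly_efficient
    fout <- dea(inst$X, inst$Y, "output")
    expect_true(all(fout$efficient[strong]))
  }
})

test_that("projection targets land on the frontier (score 1 after replacement)", {
  set.seed(606)
  for (k in 1:6) {
    inst <- random_dea_instance(5, 2, 1)
    inv_in <- c(TRUE, FALSE)
    inv_out <- TRUE  # exercise the reciprocal back-transform path too
    for (orient in c("input", "output")) {
      fit <- dea(inst$X, inst$Y, orientation = orient,
                 inverted_inputs = inv_in, inverted_outputs = inv_out)
      worst <- which.max(abs(fit$scores - 1))
      if (fit$efficient[worst]) next
      X2 <- inst$X; Y2 <- inst$Y
      X2[worst, ] <- as.numeric(fit$targets_original$inputs[worst, ])
      Y2[worst, ] <- as.numeric(fit$targets_original$outputs[worst, ])
      refit <- dea(X2, Y2, orientation = orient,
                   inverted_inputs = inv_in, inverted_outputs = inv_out)
      expect_equal(unname(refit$scores[worst]), 1, tolerance = 1e-6)
    }
  }
})

test_that("reciprocal transform is an involution and rejects non-positive data", {
  expect_equal(invert_variables(1, TRUE), 1)
  expect_equal(invert_variables(c(0.5, 2), TRUE), c(2, 0.5))
  expect_equal(invert_variables(c(0.5, 2), FALSE), c(0.5, 2))
  set.seed(7)
  v <- stats::runif(20, 0.01, 50)
  expect_equal(invert_variables(invert_variables(v, TRUE), TRUE), v)
  expect_error(invert_variables(c(1, 0), TRUE, "smr"), "smr")
  expect_error(invert_variables(-2, FALSE), "non-positive")
})

test_that("model-scale targets equal the peer-weighted data; back-transform inverts flagged columns", {
  set.seed(808)
  inst <- random_dea_instance(5, 2, 1)
  fit <- dea(inst$X, inst$Y, "input",
             inverted_inputs = c(FALSE, TRUE), inverted_outputs = TRUE)
  expect_equal(fit$targets_model$inputs, fit$lambda %*% fit$X,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fit$targets_model$outputs, fit$lambda %*% fit$Y,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fit$targets_original$inputs[, 2], 1 / fit$targets_model$inputs[, 2],
               ignore_attr = TRUE)
  expect_equal(fit$targets_original$inputs[, 1], fit$targets_model$inputs[, 1],
               ignore_attr = TRUE)
  expect_equal(fit$targets_original$outputs[, 1], 1 / fit$targets_model$outputs[, 1],
               ignore_attr = TRUE)
})

test_that("invalid envelopment data is rejected with informative errors", {
  expect_error(dea(matrix(c(1, 0), 2, 1), matrix(c(1, 1), 2, 1)),
               "strictly positive")
  expect_error(dea(matrix(1:4, 2, 2), matrix(c(1, 1), 2, 1),
                   dmu_ids = c("a", "a")), "duplicate")
  expect_error(dea(matrix(c(1, NA), 2, 1), matrix(c(1, 1), 2, 1)),
               "finite")
})

test_that("formula interface reproduces the matrix interface", {
  dat <- data.frame(unit_id = c("A", "B", "C"), x = c(2, 4, 3),
                    y = c(2, 4, 2))
  ff <- dea(y ~ x, data = dat, orientation = "input")
  expect_equal(unname(coef(ff)), c(1, 1, 2/3), tolerance = 1e-6)
  expect_equal(ff$dmu_ids, c("A", "B", "C"))
})

test_that("predict scores new units against the fitted frontier", {
  fit <- dea(worked_X, worked_Y, orientation = "input")
  # a unit identical to A must be efficient; one using more input at A's
  # output level scores 2/p
  pr <- predict(fit, newX = matrix(c(2, 5), 2, 1),
                newY = matrix(c(2, 2), 2, 1))
  expect_equal(pr$score, c(1, 2/5), tolerance = 1e-6)
  expect_equal(pr$efficient, c(TRUE, FALSE))
})
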