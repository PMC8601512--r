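# Independent brute-force oracle for the VRS envelopment LP.
#
# The optimum of a linear program lies at a vertex of its feasible region, so
# for the tiny instances used in tests the LP can be solved exactly by
# enumerating every choice of binding constraints, solving the resulting
# square linear system, keeping feasible solutions, and taking the best
# objective. No simplex code is shared with the implementation under test.

dea_oracle <- function(X, Y, o, orientation = c("input", "output")) {
  orientation <- match.arg(orientation)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  x0 <- X[o, ]; y0 <- Y[o, ]
  # variables v = (lambda_1..n, t); inequality rows G v <= h; equality sum(lambda)=1
  if (orientation == "input") {
    G <- rbind(cbind(t(X), -x0),                      # inputs: X'l <= t x0
               cbind(-t(Y), rep(0, s)),               # outputs: Y'l >= y0
               cbind(-diag(n), rep(0, n)),            # lambda >= 0
               c(rep(0, n), -1))                      # t >= 0
    h <- c(rep(0, m), -y0, rep(0, n), 0)
    better <- function(a, b) a < b
    best <- Inf
  } else {
    G <- rbind(cbind(t(X), rep(0, m)),                # inputs: X'l <= x0
               cbind(-t(Y), y0),                      # outputs: Y'l >= t y0
               cbind(-diag(n), rep(0, n)),
               c(rep(0, n), -1))
    h <- c(x0, rep(0, s), rep(0, n), 0)
    better <- function(a, b) a > b
    best <- -Inf
  }
  a_eq <- c(rep(1, n), 0)
  nv <- n + 1L
  combos <- utils::combn(nrow(G), nv - 1L)
  best_v <- NULL
  for (k in seq_len(ncol(combos))) {
    A <- rbind(G[combos[, k], , drop = FALSE], a_eq)
    rhs <- c(h[combos[, k]], 1)
    v <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(v)) next
    if (all(G %*% v <= h + 1e-8)) {
      t_val <- unname(v[nv])
      if (better(t_val, best)) { best <- t_val; best_v <- v }
    }
  }
  list(score = best, lambda = if (!is.null(best_v)) best_v[seq_len(n)])
}

random_dea_instance <- function(n = 5L, m = 2L, s = 1L) {
  list(X = matrix(stats::runif(n * m, 0.5, 5), n, m),
       Y = matrix(stats::runif(n * s, 0.5, 5), n, s))
}
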