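# Linear-programming core.
#
# The envelopment problems are tiny (a handful of constraints, one variable
# per DMU), but they must solve reliably in both phases, including
# equality-only slack-maximization LPs. solve_lp() exposes a generic
# minimize/maximize interface over <=, >= and = constraints; behind it sits
# a dense two-phase primal simplex with Bland's anti-cycling rule, so runs
# are deterministic (fixed variable order, smallest-index pivoting).

# Minimize obj'x subject to A x = b with b >= 0, x >= 0.
# Full-tableau two-phase simplex with artificial variables in every row.
simplex_core <- function(obj, A, b, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  # columns: structural (1..n), artificial (n+1..n+m), rhs (last)
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  # reduced-cost rows d = c - z, updated through every pivot:
  # row "p1" for the phase-1 cost (sum of artificials),
  # row "p2" for the true objective (artificials costed 0)
  d1 <- c(-colSums(A), rep(0, m), -sum(b))
  d2 <- c(obj, rep(0, m), 0)

  pivot <- function(pr, pc) {
    piv <- Tab[pr, pc]
    Tab[pr, ] <<- Tab[pr, ] / piv
    for (i in seq_len(m)) if (i != pr && abs(Tab[i, pc]) > 0)
      Tab[i, ] <<- Tab[i, ] - Tab[i, pc] * Tab[pr, ]
    if (abs(d1[pc]) > 0) d1 <<- d1 - d1[pc] * Tab[pr, ]
    if (abs(d2[pc]) > 0) d2 <<- d2 - d2[pc] * Tab[pr, ]
    basis[pr] <<- pc
  }

  run_phase <- function(drow_get, allowed) {
    for (it in seq_len(max_iter)) {
      d <- drow_get()
      enter <- 0L
      for (j in allowed) {            # Bland: smallest eligible index
        if (d[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return(TRUE)   # optimal
      ratios <- ifelse(Tab[, enter] > tol,
                       Tab[, n + m + 1L] / Tab[, enter], Inf)
      if (all(!is.finite(ratios))) return(NA)  # unbounded
      leave <- which(ratios < min(ratios) + 1e-12)
      if (length(leave) > 1L)          # Bland tie-break: smallest basis index
        leave <- leave[which.min(basis[leave])]
      pivot(leave[1L], enter)
    }
    FALSE                              # iteration limit
  }

  st <- run_phase(function() d1, seq_len(n + m))
  if (!isTRUE(st)) stop("LP phase 1 failed (iteration limit).")
  if (-d1[n + m + 1L] > 1e-7)
    stop("LP infeasible (artificial variables remain positive).")
  # pivot lingering zero-level artificials out of the basis; a row whose
  # structural coefficients are all zero is redundant and can stay
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      pc <- which(abs(Tab[i, seq_len(n)]) > tol)[1L]
      if (!is.na(pc)) pivot(i, pc)
    }
  }
  st <- run_phase(function() d2, seq_len(n))
  if (is.na(st)) stop("LP unbounded.")
  if (!isTRUE(st)) stop("LP phase 2 failed (iteration limit).")
  x <- numeric(n)
  in_struct <- basis <= n
  x[basis[in_struct]] <- Tab[in_struct, n + m + 1L]
  list(x = x, value = -d2[n + m + 1L])
}

# General interface: minimize (or maximize) objective'x over
#   A_le x <= b_le, A_ge x >= b_ge, A_eq x = b_eq, x >= 0.
solve_lp <- function(objective,
                     A_le = NULL, b_le = NULL,
                     A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL,
                     maximize = FALSE, tol = 1e-9) {
  nv <- length(objective)
  as_mat <- function(A) if (is.null(A)) NULL else
    matrix(as.numeric(A), ncol = nv)
  A_le <- as_mat(A_le); A_ge <- as_mat(A_ge); A_eq <- as_mat(A_eq)
  n_le <- if (is.null(A_le)) 0L else nrow(A_le)
  n_ge <- if (is.null(A_ge)) 0L else nrow(A_ge)
  n_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  A <- rbind(A_le, A_ge, A_eq)
  b <- c(b_le, b_ge, b_eq)
  m <- nrow(A)
  if (length(b) != m) stop("constraint matrix / rhs length mismatch.")
  # slack (+1) for <=, surplus (-1) for >=
  n_sl <- n_le + n_ge
  S <- matrix(0, m, n_sl)
  if (n_le) S[cbind(seq_len(n_le), seq_len(n_le))] <- 1
  if (n_ge) S[cbind(n_le + seq_len(n_ge), n_le + seq_len(n_ge))] <- -1
  A_full <- cbind(A, S)
  neg <- b < 0
  if (any(neg)) { A_full[neg, ] <- -A_full[neg, ]; b[neg] <- -b[neg] }
  obj_full <- c(if (maximize) -objective else objective, rep(0, n_sl))
  res <- simplex_core(obj_full, A_full, b, tol = tol)
  list(solution = res$x[seq_len(nv)],
       value = if (maximize) -res$value else res$value)
}
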