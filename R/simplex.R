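# Dense two-phase tableau simplex used by solve_fba().
#
# Problems are tiny (tens of reactions), so a dense tableau with Bland's
# anti-cycling rule is preferred over sparse machinery: it is exact to
# floating-point elimination error and immune to cycling on the highly
# degenerate LPs that flux balance problems produce.

# Solve  min cost'x  s.t.  A x = b, x >= 0  with b >= 0.
# Returns list(status, x, obj). status: "optimal", "infeasible", "unbounded".
lp_simplex_standard <- function(A, b, cost, tol = 1e-9, max_iter = 50000L) {
  M <- nrow(A)
  N <- ncol(A)
  stopifnot(all(b >= -tol))
  b[b < 0] <- 0

  run_phase <- function(tab, basis, cost_full, n_cols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) {
        return(list(status = "iteration_limit", tab = tab, basis = basis))
      }
      cb <- cost_full[basis]
      red <- cost_full[seq_len(n_cols)] -
        as.numeric(crossprod(cb, tab[, seq_len(n_cols), drop = FALSE]))
      ent <- which(red < -tol)
      if (!length(ent)) {
        return(list(status = "optimal", tab = tab, basis = basis))
      }
      j <- ent[1L] # Bland: lowest-index entering column
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) {
        return(list(status = "unbounded", tab = tab, basis = basis))
      }
      ratio <- tab[pos, n_cols + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])] # Bland: lowest-index leaving variable
      tab[i, ] <- tab[i, ] / tab[i, j]
      for (r in seq_len(nrow(tab))) {
        if (r != i && abs(tab[r, j]) > 0) {
          tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
        }
      }
      basis[i] <- j
    }
  }

  # Phase 1: artificial basis, minimise infeasibility.
  tab <- cbind(A, diag(M), b)
  basis <- N + seq_len(M)
  cost1 <- c(rep(0, N), rep(1, M))
  p1 <- run_phase(tab, basis, cost1, N + M)
  if (p1$status != "optimal") {
    return(list(status = p1$status, x = NULL, obj = NA_real_))
  }
  infeas <- sum(cost1[p1$basis] * p1$tab[, N + M + 1L])
  if (infeas > 1e-7) {
    return(list(status = "infeasible", x = NULL, obj = NA_real_))
  }

  # Pivot remaining artificials out of the basis; rows where no structural
  # pivot exists are redundant constraints and are dropped.
  tab <- p1$tab
  basis <- p1$basis
  keep <- rep(TRUE, nrow(tab))
  for (i in which(basis > N)) {
    cand <- setdiff(which(abs(tab[i, seq_len(N)]) > tol), basis)
    if (length(cand)) {
      j <- cand[1L]
      tab[i, ] <- tab[i, ] / tab[i, j]
      for (r in seq_len(nrow(tab))) {
        if (r != i) tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      }
      basis[i] <- j
    } else {
      keep[i] <- FALSE
    }
  }
  tab <- tab[keep, c(seq_len(N), N + M + 1L), drop = FALSE]
  basis <- basis[keep]

  # Phase 2 on the original costs.
  p2 <- run_phase(tab, basis, cost, N)
  if (p2$status != "optimal") {
    return(list(status = p2$status, x = NULL, obj = NA_real_))
  }
  x <- numeric(N)
  x[p2$basis] <- p2$tab[, N + 1L]
  list(status = "optimal", x = x, obj = sum(cost * x))
}

# Solve the bounded LP  max c'v  s.t.  S v = 0, lb <= v <= ub.
# Shift x = v - lb (all bounds made finite beforehand) and add slack
# variables for the upper bounds so the standard-form routine applies.
lp_solve_bounded <- function(S, lb, ub, objective, tol = 1e-9) {
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(objective) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", v = NULL, obj = NA_real_))
  }
  b_eq <- as.numeric(-S %*% lb)
  u <- ub - lb
  A <- rbind(
    cbind(S, matrix(0, nrow(S), n)),
    cbind(diag(n), diag(n))
  )
  b <- c(b_eq, u)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  res <- lp_simplex_standard(A, b, c(-objective, rep(0, n)), tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, v = NULL, obj = NA_real_))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", v = v, obj = sum(objective * v))
}
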