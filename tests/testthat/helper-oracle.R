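# Independent LP oracle: enumerate every basic solution (vertex) of
# {S v = 0, lb <= v <= ub} by fixing n - rank(S) variables at a bound and
# solving the remaining square system. Exponential, fine for <= 12 reactions.
# Deliberately shares no code with the package's simplex engine.
oracle_lp_max <- function(S, lb, ub, objective) {
  keep <- qr(t(S))$pivot[seq_len(qr(t(S))$rank)]
  S <- S[sort(keep), , drop = FALSE]
  n <- ncol(S)
  m <- nrow(S)
  free_k <- n - m
  best <- -Inf
  feasible <- FALSE
  for (fix_set in utils::combn(n, free_k, simplify = FALSE)) {
    basic <- setdiff(seq_len(n), fix_set)
    Sb <- S[, basic, drop = FALSE]
    if (m > 0 && abs(det(Sb)) < 1e-10) next
    grid <- if (free_k > 0) {
      as.matrix(expand.grid(rep(list(c(1, 2)), free_k)))
    } else {
      matrix(0, 1, 0)
    }
    for (g in seq_len(nrow(grid))) {
      vf <- if (free_k) ifelse(grid[g, ] == 1, lb[fix_set], ub[fix_set]) else numeric(0)
      v <- numeric(n)
      v[fix_set] <- vf
      if (m > 0) {
        rhs <- if (free_k) -S[, fix_set, drop = FALSE] %*% vf else matrix(0, m, 1)
        v[basic] <- solve(Sb, rhs)
      }
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8)) {
        feasible <- TRUE
        best <- max(best, sum(objective * v))
      }
    }
  }
  list(feasible = feasible, objective = best)
}

# random small model with integer stoichiometry, as a metabolic_model
random_small_model <- function(n_rxn, n_met) {
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), n_met * n_rxn,
                     replace = TRUE), n_met, n_rxn)
  lb <- ifelse(stats::runif(n_rxn) < 0.4, -10, 0)
  ub <- rep(10, n_rxn)
  met_ids <- sprintf("m%02d_c", seq_len(n_met))
  rxn_ids <- sprintf("r%02d", seq_len(n_rxn))
  st <- lapply(seq_len(n_rxn), function(j) {
    nz <- which(S[, j] != 0)
    stats::setNames(S[nz, j], met_ids[nz])
  })
  empty <- vapply(st, length, integer(1)) == 0
  st[empty] <- lapply(which(empty), function(j) stats::setNames(1, met_ids[1]))
  S[1, empty] <- 1
  obj <- sample(n_rxn, 1)
  model <- metabolic_model(
    metabolites = tibble::tibble(id = met_ids, name = met_ids,
                                 compartment = "c"),
    reactions = tibble::tibble(
      id = rxn_ids, name = rxn_ids, stoichiometry = st,
      lower_bound = lb, upper_bound = ub,
      is_exchange = FALSE, is_sink = FALSE
    ),
    objective = rxn_ids[obj]
  )
  # boundary invariant (single-metabolite => sink) is not meaningful for
  # random matrices; flag everything internal
  list(model = model, S = S, lb = lb, ub = ub,
       objective = as.numeric(seq_len(n_rxn) == obj))
}

# tiny 3-reaction linear chain A -> B -> C with exchanges at both ends
chain_model <- function() {
  metabolic_model(
    metabolites = tibble::tibble(
      id = c("a_c", "b_c", "c_c"), name = c("A", "B", "C"), compartment = "c"
    ),
    reactions = tibble::tibble(
      id = c("EX_a", "AB", "BC", "EX_c", "DM_b"),
      name = c("A supply", "A to B", "B to C", "C drain", "B drain"),
      stoichiometry = list(c(a_c = 1), c(a_c = -1, b_c = 1),
                           c(b_c = -1, c_c = 1), c(c_c = -1), c(b_c = -1)),
      lower_bound = c(0, 0, 0, 0, 0),
      upper_bound = c(5, 1000, 1000, 1000, 1000),
      is_exchange = c(TRUE, FALSE, FALSE, TRUE, FALSE),
      is_sink = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    objective = "EX_c"
  )
}
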