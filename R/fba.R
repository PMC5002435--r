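#' Flux balance analysis: maximise the biomass objective
#'
#' Solves the linear program `maximise v_objective` subject to the steady
#' state `S v = 0` and the model's flux bounds, with an exact two-phase
#' simplex (Bland's rule, so degenerate optima cannot cycle). Only the
#' objective value is contractual: flux vectors at degenerate optima are
#' reported but are not unique.
#'
#' @param model A [metabolic_model()].
#' @param extra_constraints Optional named list of `c(lb, ub)` pairs,
#'   keyed by reaction id, overriding the stored bounds for this call only.
#' @param big Finite stand-in for infinite bounds inside the solver
#'   (mmol gDW^-1 h^-1).
#' @param tol Pivoting tolerance.
#' @return An object of class `fba_result`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value`
#'   (BOFmax; h^-1 for biomass objectives) and `fluxes` (named vector,
#'   mmol gDW^-1 h^-1).
#' @examples
#' tm <- toy_model()
#' solve_fba(tm)$objective_value # photon-limited BOFmax
#' @export
solve_fba <- function(model, extra_constraints = NULL, big = 1e5, tol = 1e-9) {
  if (nrow(model$reactions) == 0) {
    stop("cannot run FBA on a model with no reactions")
  }
  if (is.na(model$objective) || !model$objective %in% model$reactions$id) {
    stop("model has no valid objective reaction")
  }
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  ids <- model$reactions$id
  if (!is.null(extra_constraints)) {
    unknown <- setdiff(names(extra_constraints), ids)
    if (length(unknown)) {
      stop("extra_constraints name unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    }
    # iterate positionally: duplicated names are allowed and later
    # entries override earlier ones (supply, then mode toggles)
    for (k in seq_along(extra_constraints)) {
      i <- match(names(extra_constraints)[k], ids)
      lb[i] <- extra_constraints[[k]][1]
      ub[i] <- extra_constraints[[k]][2]
    }
  }
  had_inf_ub <- !is.finite(ub)
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  S <- as.matrix(stoich_matrix(model))
  objective <- as.numeric(ids == model$objective)
  res <- lp_solve_bounded(S, lb, ub, objective, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = NULL, model_objective = model$objective),
                     class = "fba_result"))
  }
  fluxes <- stats::setNames(res$v, ids)
  obj_i <- match(model$objective, ids)
  # objective pinned to the artificial cap on an unbounded reaction ->
  # genuinely unbounded problem
  status <- if (had_inf_ub[obj_i] && res$obj >= big - 1e-6) {
    "unbounded"
  } else {
    "optimal"
  }
  structure(
    list(status = status, objective_value = res$obj, fluxes = fluxes,
         model_objective = model$objective),
    class = "fba_result"
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status:", x$status,
      " BOFmax:", format(x$objective_value, digits = 10), "\n")
  invisible(x)
}

#' Tidy an FBA result into a flux table
#'
#' @param x An `fba_result`.
#' @param ... Unused.
#' @return A tibble with columns `reaction` and `flux`.
#' @method tidy fba_result
#' @export
tidy.fba_result <- function(x, ...) {
  if (is.null(x$fluxes)) {
    return(tibble::tibble(reaction = character(), flux = numeric()))
  }
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of an FBA result
#'
#' @param x An `fba_result`.
#' @param ... Unused.
#' @return A one-row tibble: `status`, `objective_value`, `n_reactions`.
#' @method glance fba_result
#' @export
glance.fba_result <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_value = x$objective_value,
    n_reactions = length(x$fluxes)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# bounds that fix the GG supply rate as an equality on the supplying
# reaction: exchange uptake (negative flux) for exogenous GG, synthesis
# flux for endogenous GG
gg_supply_constraints <- function(qGG, supply = c("exchange", "synthesis"),
                                  gg_exchange = "EX_glcglyc(e)",
                                  ggps_rxn = "GGPS") {
  supply <- match.arg(supply)
  stopifnot(qGG >= 0)
  if (supply == "exchange") {
    stats::setNames(list(c(-qGG, -qGG)), gg_exchange)
  } else {
    stats::setNames(list(c(qGG, qGG)), ggps_rxn)
  }
}

#' BOFmax fitness ratio of GG utilization
#'
#' The fitness benefit of a utilization pathway is quantified as
#' `100 * BOFmax(utilization unconstrained, bounds [0, Inf)) /
#' BOFmax(utilization constrained to zero)`, with the GG supply fixed at
#' `qGG` as an equality in both numerator and denominator. The storage sink
#' keeps the denominator feasible: supplied GG that cannot be cleaved is
#' absorbed without contributing to biomass.
#'
#' @param model A GG-extended [metabolic_model()].
#' @param utilization_rxn_ids Reactions whose benefit is being measured
#'   (default both cleavage reactions).
#' @param qGG GG supply rate, mmol gDW^-1 h^-1.
#' @param supply `"exchange"` (exogenous GG, uptake fixed at -qGG) or
#'   `"synthesis"` (endogenous GG, synthesis flux fixed at qGG).
#' @param gg_exchange,ggps_rxn Reaction ids of the GG exchange and
#'   synthesis reactions.
#' @return The fitness ratio in percent (>= 100 up to solver tolerance).
#' @examples
#' tm <- toy_model()
#' fitness_ratio(tm, qGG = 0)    # exactly 100
#' fitness_ratio(tm, qGG = 0.01) # > 100
#' @export
fitness_ratio <- function(model,
                          utilization_rxn_ids = c("GLCGLYCHyd",
                                                  "GLCGLYCPhosphorylase"),
                          qGG = 0,
                          supply = c("exchange", "synthesis"),
                          gg_exchange = "EX_glcglyc(e)", ggps_rxn = "GGPS") {
  supply <- match.arg(supply)
  missing <- setdiff(utilization_rxn_ids, model$reactions$id)
  if (length(missing)) {
    stop("utilization reaction(s) not in model: ",
         paste(missing, collapse = ", "))
  }
  base <- gg_supply_constraints(qGG, supply, gg_exchange, ggps_rxn)
  open <- c(base, stats::setNames(
    rep(list(c(0, Inf)), length(utilization_rxn_ids)), utilization_rxn_ids))
  closed <- c(base, stats::setNames(
    rep(list(c(0, 0)), length(utilization_rxn_ids)), utilization_rxn_ids))
  num <- solve_fba(model, open)
  den <- solve_fba(model, closed)
  if (num$status != "optimal" || den$status != "optimal") {
    stop("FBA not optimal (numerator: ", num$status,
         ", denominator: ", den$status, ")")
  }
  if (abs(den$objective_value) < 1e-12) {
    stop("fitness ratio undefined: reference BOFmax is zero")
  }
  bof_ratio(num, den, distinguishing_num = utilization_rxn_ids,
            distinguishing_den = character(0), nested = TRUE)
}

# Ratio of two BOFmax values with float noise removed by theorem:
# (a) if the numerator problem relaxes the denominator problem (`nested`),
#     num >= den holds exactly, so the numeric values are clamped to it;
# (b) if the numerator optimum carries ~zero flux through the reactions
#     closed only in the denominator (and vice versa), each optimum is
#     feasible for the other problem, hence the optima are exactly equal
#     and the ratio is exactly 100.
bof_ratio <- function(num, den, distinguishing_num, distinguishing_den,
                      nested = FALSE, flux_tol = 1e-7) {
  num_obj <- num$objective_value
  den_obj <- den$objective_value
  zero_flux <- function(res, ids) {
    !length(ids) || all(abs(res$fluxes[ids]) <= flux_tol, na.rm = TRUE)
  }
  if (zero_flux(num, distinguishing_num) && zero_flux(den, distinguishing_den)) {
    return(100)
  }
  if (nested) num_obj <- max(num_obj, den_obj)
  100 * num_obj / den_obj
}
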