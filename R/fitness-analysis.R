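# In-silico experiments: cleavage-mode sweep, glycerol-utilization benefit,
# and the simulated strain-ratio table over the measured culture intervals.

#' Default qGG sweep grid
#'
#' 50 log-spaced points from 1e-4 to 1.5 mmol gDW^-1 h^-1 — from far below
#' the measured uptake rates to two orders of magnitude above the largest
#' one, covering the "very high uptake rates" regime.
#'
#' @param n Number of grid points.
#' @param from,to Grid limits (mmol gDW^-1 h^-1).
#' @return Strictly increasing numeric vector.
#' @export
default_qgg_grid <- function(n = 50, from = 1e-4, to = 1.5) {
  exp(seq(log(from), log(to), length.out = n))
}

sweep_ratio <- function(model, qGG_grid, open_ids, closed_num, closed_den,
                        supply, gg_exchange, ggps_rxn) {
  stopifnot(all(qGG_grid >= 0), !is.unsorted(qGG_grid, strictly = TRUE))
  ratio <- vapply(qGG_grid, function(q) {
    base <- gg_supply_constraints(q, supply, gg_exchange, ggps_rxn)
    con_num <- c(base,
                 stats::setNames(rep(list(c(0, Inf)), length(open_ids)), open_ids),
                 stats::setNames(rep(list(c(0, 0)), length(closed_num)), closed_num))
    con_den <- c(base,
                 stats::setNames(rep(list(c(0, Inf)), length(open_ids)), open_ids),
                 stats::setNames(rep(list(c(0, 0)), length(closed_den)), closed_den))
    num <- solve_fba(model, con_num)
    den <- solve_fba(model, con_den)
    if (num$status != "optimal" || den$status != "optimal") {
      stop("FBA not optimal at qGG = ", q)
    }
    if (abs(den$objective_value) < 1e-12) {
      stop("sweep ratio undefined at qGG = ", q, ": denominator BOFmax is zero")
    }
    bof_ratio(num, den,
              distinguishing_num = setdiff(closed_den, closed_num),
              distinguishing_den = setdiff(closed_num, closed_den),
              nested = length(setdiff(closed_num, closed_den)) == 0)
  }, numeric(1))
  ratio
}

#' Sweep GG cleavage modes: phosphorolysis vs hydrolysis
#'
#' For each supply rate on the grid, computes
#' `100 * BOFmax(phosphorylase open, hydrolase closed) /
#' BOFmax(hydrolase open, phosphorylase closed)` with GG supply fixed at
#' qGG. Phosphorolysis yields glucose-1-phosphate and spares the
#' glucokinase ATP, so where that saving matters the ratio exceeds 100%.
#'
#' @param model A GG-extended [metabolic_model()].
#' @param qGG_grid Strictly increasing non-negative supply rates
#'   (mmol gDW^-1 h^-1); defaults to [default_qgg_grid()].
#' @param supply GG supply route, see [fitness_ratio()].
#' @param gg_exchange,ggps_rxn Reaction ids.
#' @return A `gg_sweep` tibble: columns `qGG`, `ratio_percent`, `mode`.
#' @examples
#' sw <- sweep_cleavage_modes(toy_model(), qGG_grid = c(0.001, 0.01, 0.1))
#' all(sw$ratio_percent >= 100)
#' @export
sweep_cleavage_modes <- function(model, qGG_grid = default_qgg_grid(),
                                 supply = c("exchange", "synthesis"),
                                 gg_exchange = "EX_glcglyc(e)",
                                 ggps_rxn = "GGPS") {
  supply <- match.arg(supply)
  ratio <- sweep_ratio(
    model, qGG_grid,
    open_ids = character(0),
    closed_num = "GLCGLYCHyd",
    closed_den = "GLCGLYCPhosphorylase",
    supply = supply, gg_exchange = gg_exchange, ggps_rxn = ggps_rxn
  )
  out <- tibble::tibble(qGG = qGG_grid, ratio_percent = ratio,
                        mode = "phosphorolysis/hydrolysis")
  class(out) <- c("gg_sweep", class(out))
  out
}

#' Sweep the benefit of glycerol re-assimilation
#'
#' Ratio of BOFmax with glycerol kinase open versus fixed to zero (the
#' glycerol moiety then exits via its exchange), GG supply fixed at each
#' grid point. Quantifies how much the cell gains from salvaging the C3
#' part of GG on top of the glucose moiety.
#'
#' @inheritParams sweep_cleavage_modes
#' @param glpk_rxn Id of the glycerol kinase reaction.
#' @param cleavage Which cleavage route is open while glycerol use is
#'   toggled: `"both"`, `"hydrolysis"` or `"phosphorolysis"`.
#' @return A `gg_sweep` tibble: columns `qGG`, `ratio_percent`, `mode`.
#' @export
glycerol_utilization_benefit <- function(model, qGG_grid = default_qgg_grid(),
                                         glpk_rxn = "GLPK",
                                         cleavage = c("both", "hydrolysis",
                                                      "phosphorolysis"),
                                         supply = c("exchange", "synthesis"),
                                         gg_exchange = "EX_glcglyc(e)",
                                         ggps_rxn = "GGPS") {
  supply <- match.arg(supply)
  cleavage <- match.arg(cleavage)
  closed_cleavage <- switch(cleavage,
    both = character(0),
    hydrolysis = "GLCGLYCPhosphorylase",
    phosphorolysis = "GLCGLYCHyd"
  )
  ratio <- sweep_ratio(
    model, qGG_grid,
    open_ids = glpk_rxn,
    closed_num = closed_cleavage,
    closed_den = c(closed_cleavage, glpk_rxn),
    supply = supply, gg_exchange = gg_exchange, ggps_rxn = ggps_rxn
  )
  out <- tibble::tibble(qGG = qGG_grid, ratio_percent = ratio,
                        mode = "glycerol kinase open/closed")
  class(out) <- c("gg_sweep", class(out))
  out
}

#' The measured culture intervals and their GG uptake rates
#'
#' The five two-day intervals of the batch experiment with the specific GG
#' uptake rates derived from the glycerol production of the
#' synthesis-deficient (ggpS) strain fed exogenous GG.
#'
#' @return A tibble with columns `t0`, `t1` (days) and `qGG`
#'   (mmol gDW^-1 h^-1).
#' @export
table5_intervals <- function() {
  tibble::tibble(
    t0 = c(0, 2, 4, 6, 8),
    t1 = c(2, 4, 6, 8, 10),
    qGG = c(0.008, 0.015, 0.014, 0.009, 0.003)
  )
}

#' Simulate per-interval strain growth-rate ratios
#'
#' For each culture interval and strain, computes
#' `100 * BOFmax(strain) / BOFmax(reference)` with the GG supply fixed at
#' that interval's qGG. The reference is the cleavage-deficient
#' (slr1670) mutant, whose supplied GG ends in the storage sink.
#'
#' @param model A GG-extended [metabolic_model()].
#' @param intervals Tibble with columns `t0`, `t1`, `qGG`; defaults to
#'   [table5_intervals()].
#' @param strains Character vector of strain names to compare.
#' @param reference Reference strain name.
#' @param cleavage Which cleavage reactions are allowed to carry flux in
#'   strains with functional slr1670: `"both"` (default), `"hydrolysis"` or
#'   `"phosphorolysis"`.
#' @param supply GG supply route (see [fitness_ratio()]); the default
#'   `"exchange"` mirrors cultures fed exogenous GG, from which the qGG
#'   values derive.
#' @param gg_exchange,ggps_rxn,glpk_rxn Reaction-id mapping.
#' @return A tibble with columns `interval`, `t0`, `t1`, `qGG`, `strain`,
#'   `sim_ratio_percent`.
#' @examples
#' simulate_table5(toy_model(), strains = c("WT", "dggpS"))
#' @export
simulate_table5 <- function(model, intervals = table5_intervals(),
                            strains = c("WT", "dggpS", "dglpK"),
                            reference = "dslr1670",
                            cleavage = c("both", "hydrolysis",
                                         "phosphorolysis"),
                            supply = c("exchange", "synthesis"),
                            gg_exchange = "EX_glcglyc(e)",
                            ggps_rxn = "GGPS", glpk_rxn = "GLPK") {
  cleavage <- match.arg(cleavage)
  supply <- match.arg(supply)
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("t0", "t1", "qGG") %in% names(intervals)),
            all(intervals$qGG >= 0), all(intervals$t0 < intervals$t1))
  strain_map <- gg_strains(ggps_rxn = ggps_rxn, glpk_rxn = glpk_rxn)
  cleavage_closed <- switch(cleavage,
    both = character(0),
    hydrolysis = "GLCGLYCPhosphorylase",
    phosphorolysis = "GLCGLYCHyd"
  )
  bof <- function(strain, q) {
    i <- match(strain, strain_map$strain)
    if (is.na(i)) stop("unknown strain: ", strain)
    ko <- strain_map$knockouts[[i]]
    # endogenous supply through a knocked-out synthesis reaction is
    # impossible; such strains must take GG up from the medium
    strain_supply <- if (supply == "synthesis" && ggps_rxn %in% ko) {
      "exchange"
    } else {
      supply
    }
    con <- gg_supply_constraints(q, strain_supply, gg_exchange, ggps_rxn)
    con <- c(con, stats::setNames(rep(list(c(0, 0)), length(ko)), ko))
    extra_closed <- setdiff(cleavage_closed, ko)
    con <- c(con, stats::setNames(rep(list(c(0, 0)), length(extra_closed)),
                                  extra_closed))
    res <- solve_fba(model, con)
    if (res$status != "optimal") {
      stop("FBA not optimal for strain ", strain, " at qGG = ", q,
           " (", res$status, ")")
    }
    res$objective_value
  }
  rows <- purrr::pmap(intervals, function(t0, t1, qGG, ...) {
    ref_val <- bof(reference, qGG)
    if (abs(ref_val) < 1e-12) {
      stop("reference BOFmax is zero in interval ", t0, "-", t1)
    }
    tibble::tibble(
      interval = paste0(t0, "-", t1), t0 = t0, t1 = t1, qGG = qGG,
      strain = strains,
      sim_ratio_percent = vapply(strains, function(s) {
        100 * bof(s, qGG) / ref_val
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Plot a qGG sweep
#'
#' @param object A `gg_sweep` tibble from [sweep_cleavage_modes()] or
#'   [glycerol_utilization_benefit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gg_sweep
#' @export
autoplot.gg_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$qGG,
                                       y = .data$ratio_percent,
                                       colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(q[GG] ~ "(mmol gDW"^-1 ~ "h"^-1 * ")"),
      y = "BOFmax ratio (%)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
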