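# Synthetic inputs: a toy photoautotroph model with hand-derivable LP
# optima, and a seeded batch-culture simulator.

#' Toy photoautotrophic model with a GG salvage branch
#'
#' A deliberately small stoichiometric model whose FBA optima are
#' hand-derivable, standing in for the genome-scale Synechocystis
#' reconstruction. Light is converted to ATP (1 ATP per photon), carbon is
#' fixed at 2 ATP per CH2O unit, and one biomass unit costs 1 CH2O plus
#' 1 ATP — so without GG the photon-limited optimum is
#' `BOFmax = photon_bound / 3`. GG synthesis costs 9 CH2O + 1 ATP per GG
#' (the nine fixed carbons); salvage recovers the carbons via hydrolysis
#' (glucose then needs the glucokinase ATP) or phosphorolysis
#' (glucose-1-phosphate enters for free), and the glycerol moiety needs
#' the glycerol-kinase ATP. All stoichiometric coefficients are small
#' integers so optima are exactly representable.
#'
#' With exogenous GG fixed at rate q the optima are
#' `(P + 17 q) / 3` (phosphorolysis + glycerol use),
#' `(P + 16 q) / 3` (hydrolysis + glycerol use) and
#' `(P + 12 q) / 3` (phosphorolysis, glycerol excreted), where `P` is the
#' photon bound: each salvaged CH2O spares 2 ATP of fixation, minus the
#' kinase costs.
#'
#' @param photon_bound Maximum photon uptake flux `P`
#'   (mmol gDW^-1 h^-1, default 100).
#' @param atp_per_photon ATP formed per photon (default 1).
#' @param atp_per_co2 ATP cost per CH2O fixed (default 2).
#' @param extended If `TRUE` (default) the GG salvage extension of
#'   [gg_extension_specs()] is applied; `FALSE` returns the base model
#'   without the seven salvage reactions.
#' @return A [metabolic_model()].
#' @examples
#' tm <- toy_model()
#' solve_fba(tm)$objective_value # 100 / 3
#' @export
toy_model <- function(photon_bound = 100, atp_per_photon = 1,
                      atp_per_co2 = 2, extended = TRUE) {
  stopifnot(photon_bound >= 0, atp_per_photon > 0, atp_per_co2 > 0)
  mets <- tibble::tibble(
    id = c("photon_e", "co2_e", "pi_e", "h2o_e", "glyc_e",
           "atp_c", "ch2o_c", "glcglyc_c", "glc__D_c", "g6p_c", "g1p_c",
           "glyc_c", "glyc3p_c", "pi_c", "h2o_c"),
    name = c("photon", "CO2", "phosphate", "water", "glycerol",
             "ATP (energy unit)", "fixed carbon (CH2O unit)",
             "glucosylglycerol", "D-glucose", "glucose 6-phosphate",
             "glucose 1-phosphate", "glycerol", "glycerol 3-phosphate",
             "phosphate", "water"),
    compartment = c(rep("e", 5), rep("c", 10)),
    formula = c(NA, "CO2", "HO4P", "H2O", "C3H8O3",
                NA, "CH2O", "C9H18O8", "C6H12O6", "C6H11O9P", "C6H11O9P",
                "C3H8O3", "C3H7O6P", "HO4P", "H2O"),
    charge = NA_integer_
  )
  rxns <- tibble::tibble(
    id = c("EX_photon(e)", "EX_co2(e)", "EX_pi(e)", "EX_h2o(e)", "EX_glyc(e)",
           "PSATP", "CBB", "BIOMASS", "GGPS",
           "GLCK", "PGM", "G6PCAT", "GLPK", "G3PCAT", "GLYCt",
           "PIt", "H2Ot"),
    name = c("photon exchange", "CO2 exchange", "phosphate exchange",
             "water exchange", "glycerol exchange",
             "light-driven ATP synthesis", "carbon fixation (lumped CBB)",
             "biomass equation", "GG synthesis (lumped GgpS/GgpP)",
             "glucokinase", "phosphoglucomutase", "glucose 6-P catabolism",
             "glycerol kinase (GlpK)", "glycerol 3-P catabolism",
             "glycerol export (diffusion)", "phosphate transport",
             "water transport"),
    stoichiometry = list(
      c(photon_e = -1),
      c(co2_e = -1),
      c(pi_e = -1),
      c(h2o_e = -1),
      c(glyc_e = -1),
      stats::setNames(c(-1, atp_per_photon), c("photon_e", "atp_c")),
      stats::setNames(c(-1, -atp_per_co2, 1), c("co2_e", "atp_c", "ch2o_c")),
      c(ch2o_c = -1, atp_c = -1),
      c(ch2o_c = -9, atp_c = -1, glcglyc_c = 1),
      c(glc__D_c = -1, atp_c = -1, g6p_c = 1),
      c(g1p_c = -1, g6p_c = 1),
      c(g6p_c = -1, ch2o_c = 6),
      c(glyc_c = -1, atp_c = -1, glyc3p_c = 1),
      c(glyc3p_c = -1, ch2o_c = 3),
      c(glyc_c = -1, glyc_e = 1),
      c(pi_e = -1, pi_c = 1),
      c(h2o_e = -1, h2o_c = 1)
    ),
    lower_bound = c(-photon_bound, -1000, -1000, -1000, 0,
                    0, 0, 0, 0, 0, -1000, 0, 0, 0, 0, -1000, -1000),
    upper_bound = c(0, rep(1000, 16)),
    gene_association = c(rep(NA_character_, 8), "ggpS ggpP",
                         NA, NA, NA, "glpK", NA, NA, NA, NA),
    is_exchange = c(rep(TRUE, 5), rep(FALSE, 12)),
    is_sink = FALSE
  )
  model <- metabolic_model(mets, rxns, objective = "BIOMASS")
  if (extended) model <- extend_with_gg(model)
  model
}

#' Simulate a batch-culture time series
#'
#' Optical density grows exponentially from `od0` at rate `mu_true` until a
#' light-limitation threshold `od_linear`, then linearly with the slope at
#' the switch point (dense cultures shade themselves, so growth becomes
#' photon- rather than biomass-limited). Extracellular glycerol accumulates
#' at `qGG_true` per unit biomass: `d glycerol/dt = qGG_true * 24 *
#' dw_per_od * OD(t)` mmol/L/day, i.e. proportional to integrated biomass.
#' Both signals carry multiplicative log-normal measurement noise
#' (positive-valued measurements), with the generating curves recoverable
#' exactly at zero noise.
#'
#' @param mu_true True specific growth rate, 1/day.
#' @param od0 Inoculation OD730.
#' @param qGG_true True specific GG consumption rate, mmol gDW^-1 h^-1
#'   (one glycerol released per GG cleaved).
#' @param noise_sd_od,noise_sd_glyc Relative (log-scale) noise sd; defaults
#'   2% for OD and 5% for glycerol.
#' @param sampling_times Sampling times in days.
#' @param od_linear OD above which growth turns linear (light limitation).
#' @param dw_per_od Dry weight per OD unit, g/L.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param strain,condition,replicate Labels attached to the series.
#' @return A tibble with columns `strain`, `condition`, `replicate`,
#'   `time_days`, `od730`, `glycerol_mM`.
#' @examples
#' sim <- simulate_culture(seed = 1, noise_sd_od = 0, noise_sd_glyc = 0)
#' growth_rate(sim, c(0, 2))$mu_per_day # mu_true
#' @export
simulate_culture <- function(mu_true = 0.6, od0 = 0.1, qGG_true = 0.01,
                             noise_sd_od = 0.02, noise_sd_glyc = 0.05,
                             sampling_times = seq(0, 10, by = 0.5),
                             od_linear = 1.5, dw_per_od = 0.2,
                             seed, strain = "dggpS", condition = "GG",
                             replicate = "r1") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(od0 > 0, qGG_true >= 0, mu_true >= 0,
            !is.unsorted(sampling_times, strictly = TRUE))
  t_switch <- if (mu_true > 0 && od_linear > od0) {
    log(od_linear / od0) / mu_true
  } else {
    Inf
  }
  od_curve <- function(t) {
    ifelse(t <= t_switch,
           od0 * exp(mu_true * t),
           od_linear + mu_true * od_linear * (t - t_switch))
  }
  # glycerol(t) = qGG * 24 * dw_per_od * integral_0^t OD dt (closed form)
  od_integral <- function(t) {
    exp_part <- if (mu_true > 0) {
      od0 * (exp(mu_true * pmin(t, t_switch)) - 1) / mu_true
    } else {
      od0 * pmin(t, t_switch)
    }
    if (!is.finite(t_switch)) return(exp_part)
    lin <- pmax(t - t_switch, 0)
    exp_part + od_linear * lin + mu_true * od_linear * lin^2 / 2
  }
  od <- od_curve(sampling_times)
  glyc <- qGG_true * 24 * dw_per_od * od_integral(sampling_times)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(sampling_times)
  od_obs <- od * exp(stats::rnorm(n, 0, noise_sd_od))
  glyc_obs <- glyc * exp(stats::rnorm(n, 0, noise_sd_glyc))
  tibble::tibble(
    strain = strain, condition = condition, replicate = replicate,
    time_days = sampling_times, od730 = od_obs, glycerol_mM = glyc_obs
  )
}

#' Plot a simulated or measured culture series
#'
#' OD730 (log scale) and extracellular glycerol against time, faceted by
#' strain/condition.
#'
#' @param data Culture tibble (see [growth_rate()] for the columns).
#' @return A ggplot.
#' @export
plot_culture <- function(data) {
  long <- tidyr::pivot_longer(tibble::as_tibble(data),
                              c("od730", "glycerol_mM"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days, y = .data$value,
                                     colour = .data$replicate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_grid(measure ~ strain + condition, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL, colour = "replicate") +
    ggplot2::theme_minimal()
}
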