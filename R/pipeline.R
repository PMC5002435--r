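# End-to-end pipeline: load/extend model, run the strain-ratio table and
# the qGG sweeps, analyse culture tables, and write a reproducible bundle.

#' Assemble a pipeline run configuration
#'
#' @param model_path Path to a model file, or `NULL` to use the built-in
#'   toy model.
#' @param dialect Model dialect passed to [read_metabolic_model()].
#' @param photon_bound Photon uptake bound (mmol gDW^-1 h^-1) applied to
#'   `photon_exchange`; `NULL` keeps the model's shipped bound.
#' @param photon_exchange Id of the photon exchange reaction.
#' @param cleavage_mode `"both"`, `"hydrolysis"` or `"phosphorolysis"`.
#' @param strains Strain names for the ratio table.
#' @param reference Reference strain.
#' @param qGG Either a numeric vector of per-interval uptake rates (paired
#'   with `intervals`) or the path of a culture CSV from which rates are
#'   estimated per interval.
#' @param intervals Tibble with `t0`, `t1` (days); defaults to
#'   [table5_intervals()] (whose qGG column is used when `qGG` is NULL).
#' @param sweep_grid qGG grid for the sweeps.
#' @param supply GG supply route, see [fitness_ratio()].
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest and used for any
#'   simulation the run performs.
#' @param ggps_rxn,glpk_rxn,gg_exchange Reaction-id mapping.
#' @return A `gg_run_config` list.
#' @export
gg_run_config <- function(model_path = NULL, dialect = "auto",
                          photon_bound = NULL,
                          photon_exchange = "EX_photon(e)",
                          cleavage_mode = "both",
                          strains = c("WT", "dggpS", "dglpK"),
                          reference = "dslr1670",
                          qGG = NULL, intervals = table5_intervals(),
                          sweep_grid = default_qgg_grid(),
                          supply = "exchange",
                          out_dir = "ggflux-run", seed = 1,
                          ggps_rxn = "GGPS", glpk_rxn = "GLPK",
                          gg_exchange = "EX_glcglyc(e)") {
  cfg <- list(
    model_path = model_path, dialect = dialect,
    photon_bound = photon_bound, photon_exchange = photon_exchange,
    cleavage_mode = match.arg(cleavage_mode,
                              c("both", "hydrolysis", "phosphorolysis")),
    strains = strains, reference = reference,
    qGG = qGG, intervals = tibble::as_tibble(intervals),
    sweep_grid = sweep_grid, supply = supply,
    out_dir = out_dir, seed = as.integer(seed),
    ggps_rxn = ggps_rxn, glpk_rxn = glpk_rxn, gg_exchange = gg_exchange
  )
  known <- gg_strains()$strain
  bad <- setdiff(c(cfg$strains, cfg$reference), known)
  if (length(bad)) {
    stop("unknown strain name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  structure(cfg, class = "gg_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [gg_run_config()]; `intervals`
#' may be a list of `{t0, t1, qGG}` records.
#'
#' @param path YAML file.
#' @return A `gg_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$intervals)) {
    y$intervals <- dplyr::bind_rows(lapply(y$intervals, tibble::as_tibble))
  }
  args <- y[intersect(names(y), names(formals(gg_run_config)))]
  do.call(gg_run_config, args)
}

#' Run the full analysis pipeline
#'
#' Loads (or builds) the model, applies the GG extension, writes the
#' extended model, simulates the per-interval strain ratio table, runs both
#' qGG sweeps, optionally estimates qGG from a culture table, and writes a
#' manifest capturing the configuration, model checksum, solver and
#' tolerances. All outputs are deterministic given (config, seed, model
#' file).
#'
#' @param config A `gg_run_config` (or path to a YAML config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the output paths and the result tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "gg_run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[1/5] model: ",
      if (is.null(config$model_path)) "built-in toy" else config$model_path)
  if (is.null(config$model_path)) {
    model <- toy_model(photon_bound = config$photon_bound %||% 100)
    model_checksum <- "builtin-toy"
  } else {
    if (!file.exists(config$model_path)) {
      stop("model file not found: ", config$model_path)
    }
    model <- read_metabolic_model(config$model_path, config$dialect)
    model <- extend_with_gg(model)
    if (!is.null(config$photon_bound)) {
      i <- match(config$photon_exchange, model$reactions$id)
      if (is.na(i)) stop("photon exchange not in model: ",
                         config$photon_exchange)
      model$reactions$lower_bound[i] <- -config$photon_bound
    }
    model_checksum <- unname(tools::md5sum(config$model_path))
  }
  model_out <- file.path(config$out_dir, "extended_model.json")
  write_metabolic_model(model, model_out, "bigg-json")

  say("[2/5] per-interval strain ratios")
  intervals <- config$intervals
  if (is.character(config$qGG)) {
    culture <- read_culture_csv(config$qGG)
    est <- dplyr::bind_rows(lapply(seq_len(nrow(intervals)), function(i) {
      q <- estimate_qGG(culture, c(intervals$t0[i], intervals$t1[i]))
      tibble::tibble(t0 = intervals$t0[i], t1 = intervals$t1[i],
                     qGG = mean(q$qGG))
    }))
    intervals$qGG <- est$qGG
    qgg_out <- file.path(config$out_dir, "qgg_estimates.tsv")
    utils::write.table(est, qgg_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (is.numeric(config$qGG)) {
    stopifnot(length(config$qGG) == nrow(intervals))
    intervals$qGG <- config$qGG
  }
  tab5 <- simulate_table5(
    model, intervals = intervals, strains = config$strains,
    reference = config$reference, cleavage = config$cleavage_mode,
    supply = config$supply, gg_exchange = config$gg_exchange,
    ggps_rxn = config$ggps_rxn, glpk_rxn = config$glpk_rxn
  )
  tab5_out <- file.path(config$out_dir, "strain_ratios.tsv")
  utils::write.table(tab5, tab5_out, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("[3/5] cleavage-mode sweep")
  sw_cleave <- sweep_cleavage_modes(
    model, config$sweep_grid, supply = config$supply,
    gg_exchange = config$gg_exchange, ggps_rxn = config$ggps_rxn
  )
  cleave_out <- file.path(config$out_dir, "sweep_cleavage.tsv")
  utils::write.table(sw_cleave, cleave_out, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("[4/5] glycerol-utilization sweep")
  sw_glyc <- glycerol_utilization_benefit(
    model, config$sweep_grid, glpk_rxn = config$glpk_rxn,
    cleavage = config$cleavage_mode, supply = config$supply,
    gg_exchange = config$gg_exchange, ggps_rxn = config$ggps_rxn
  )
  glyc_out <- file.path(config$out_dir, "sweep_glycerol.tsv")
  utils::write.table(sw_glyc, glyc_out, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("[5/5] manifest")
  manifest <- list(
    package = "ggflux",
    version = as.character(utils::packageVersion("ggflux")),
    solver = list(name = "ggflux dense two-phase simplex (Bland)",
                  feasibility_tol = 1e-9),
    seed = config$seed,
    model_checksum = model_checksum,
    # out_dir is where the run lands, not what it computes; leaving it out
    # keeps manifests of identical analyses byte-identical
    config = config[setdiff(names(config),
                            c("intervals", "sweep_grid", "out_dir"))],
    intervals = intervals,
    sweep_grid_range = range(config$sweep_grid),
    n_sweep_points = length(config$sweep_grid)
  )
  manifest_out <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_out, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  invisible(list(
    paths = list(model = model_out, strain_ratios = tab5_out,
                 sweep_cleavage = cleave_out, sweep_glycerol = glyc_out,
                 manifest = manifest_out),
    strain_ratios = tab5, sweep_cleavage = sw_cleave,
    sweep_glycerol = sw_glyc, model = model
  ))
}
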