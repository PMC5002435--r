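# The glucosylglycerol (GG) salvage extension: the seven reactions that give
# the degradation pathway flux, plus the knockout-strain encodings.

#' Built-in GG transport/degradation/storage reaction set
#'
#' The seven reactions that make GG salvage representable in a
#' Synechocystis-style reconstruction: extracellular exchange,
#' extracellular/periplasm transport, ABC uptake into the cytosol,
#' diffusive leakage out of the cytosol, a cytosolic storage sink (so that
#' GG accumulation is representable at steady state), and the two
#' alternative cleavage reactions — hydrolysis
#' (`h2o_c + glcglyc_c -> glc__D_c + glyc_c`) and phosphorolysis
#' (`pi_c + glcglyc_c -> g1p_c + glyc_c`), both associated with the
#' *slr1670* gene. Irreversible reactions carry a zero lower bound; the
#' storage sink has an unbounded upper limit and contributes nothing to
#' biomass, so it absorbs GG without rewarding its synthesis.
#'
#' @return A tibble with columns `id`, `name`, `stoichiometry` (list of
#'   named numeric vectors), `lower_bound`, `upper_bound`,
#'   `gene_association`, `is_exchange`, `is_sink`, `add_if_absent`.
#' @export
gg_extension_specs <- function() {
  tibble::tibble(
    id = c("EX_glcglyc(e)", "GLCGLYCtex", "GLCGLYCABCpp", "glcglyctpp",
           "GLCGLYCstorage", "GLCGLYCHyd", "GLCGLYCPhosphorylase"),
    name = c(
      "Glucosylglycerol exchange",
      "GG transport, extracellular to periplasm",
      "GG ABC uptake (GgtABCD), periplasm to cytosol",
      "GG transport via diffusion (cytosol to periplasm)",
      "Glucosylglycerol storage (cytosol to sink)",
      "Glucosylglycerol Hydrolase",
      "Glucosylglycerol Phosphorylase"
    ),
    stoichiometry = list(
      c(glcglyc_e = -1),
      c(glcglyc_e = -1, glcglyc_p = 1),
      c(glcglyc_p = -1, glcglyc_c = 1),
      c(glcglyc_c = -1, glcglyc_p = 1),
      c(glcglyc_c = -1),
      c(h2o_c = -1, glcglyc_c = -1, glc__D_c = 1, glyc_c = 1),
      c(pi_c = -1, glcglyc_c = -1, g1p_c = 1, glyc_c = 1)
    ),
    lower_bound = c(0, -1000, 0, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, Inf, 1000, 1000),
    gene_association = c(NA, NA, "ggtABCD", NA, NA, "slr1670", "slr1670"),
    is_exchange = c(TRUE, rep(FALSE, 6)),
    is_sink = c(rep(FALSE, 4), TRUE, FALSE, FALSE),
    add_if_absent = TRUE
  )
}

#' Extend a model with the GG salvage reactions
#'
#' Adds the reactions of [gg_extension_specs()] (or a user-supplied spec
#' table of the same shape). Specs flagged `add_if_absent` whose id already
#' exists in the model leave it unchanged, so applying the extension to a
#' reconstruction that already carries GG synthesis and exchange does not
#' duplicate them, and the operation is idempotent. Metabolites referenced
#' by a new reaction but absent from the model are created from the bundled
#' formula table ([gg_formula_table()]); an unknown metabolite is an error.
#'
#' @param model A [metabolic_model()].
#' @param specs Extension reaction table; defaults to [gg_extension_specs()].
#' @return The extended [metabolic_model()].
#' @examples
#' base <- toy_model(extended = FALSE)
#' ext <- extend_with_gg(base)
#' nrow(ext$reactions) - nrow(base$reactions) # 7
#' @export
extend_with_gg <- function(model, specs = gg_extension_specs()) {
  specs <- tibble::as_tibble(specs)
  if (!"add_if_absent" %in% names(specs)) specs$add_if_absent <- TRUE
  drop <- specs$add_if_absent & specs$id %in% model$reactions$id
  clash <- !specs$add_if_absent & specs$id %in% model$reactions$id
  if (any(clash)) {
    stop("reaction id(s) already present: ",
         paste(specs$id[clash], collapse = ", "))
  }
  specs <- specs[!drop, , drop = FALSE]
  if (nrow(specs) == 0) return(model)

  needed <- setdiff(unique(unlist(lapply(specs$stoichiometry, names))),
                    model$metabolites$id)
  if (length(needed)) {
    ann <- gg_formula_table()
    new_mets <- dplyr::bind_rows(lapply(needed, function(id) {
      parts <- split_met_id(id)
      hit <- match(parts$stem, ann$stem)
      if (is.na(hit)) {
        stop("cannot create metabolite '", id,
             "': no formula annotation for stem '", parts$stem, "'")
      }
      tibble::tibble(id = id, name = parts$stem,
                     compartment = parts$compartment,
                     formula = ann$formula[hit], charge = NA_integer_)
    }))
    model$metabolites <- dplyr::bind_rows(model$metabolites, new_mets)
  }

  new_rxns <- tibble::tibble(
    id = specs$id, name = specs$name, stoichiometry = specs$stoichiometry,
    lower_bound = specs$lower_bound, upper_bound = specs$upper_bound,
    gene_association = specs$gene_association,
    is_exchange = specs$is_exchange %||% grepl("^EX_", specs$id),
    is_sink = specs$is_sink %||%
      (vapply(specs$stoichiometry, length, integer(1)) == 1L &
         !grepl("^EX_", specs$id))
  )
  model$reactions <- dplyr::bind_rows(model$reactions, new_rxns)
  validate_metabolic_model(model)
  model
}

#' Strain genotype definitions
#'
#' Maps the study's strain names to the reaction knockouts they imply.
#' Both GG cleavage reactions carry the *slr1670* gene association, so the
#' `dslr1670` knockout silences hydrolysis and phosphorolysis together, and
#' the double mutant is the union of the two single mutants.
#'
#' @param ggps_rxn Id of the GG synthesis reaction in the target model
#'   (default `"GGPS"`, the toy model's lumped GgpS/GgpP reaction).
#' @param glpk_rxn Id of the glycerol kinase reaction (default `"GLPK"`).
#' @return A tibble with columns `strain` and `knockouts` (list column).
#' @export
gg_strains <- function(ggps_rxn = "GGPS", glpk_rxn = "GLPK") {
  tibble::tibble(
    strain = c("WT", "dggpS", "dglpK", "dslr1670", "dglpK_dslr1670"),
    knockouts = list(
      character(0),
      ggps_rxn,
      glpk_rxn,
      c("GLCGLYCHyd", "GLCGLYCPhosphorylase"),
      c(glpk_rxn, "GLCGLYCHyd", "GLCGLYCPhosphorylase")
    )
  )
}

#' Define a strain as a set of flux constraints
#'
#' @param name Strain name. One of `"WT"`, `"dggpS"`, `"dglpK"`,
#'   `"dslr1670"`, `"dglpK_dslr1670"` or `"custom"`.
#' @param knockouts Reaction ids forced to zero flux. Required for
#'   `"custom"`; for named genotypes defaults to the [gg_strains()] mapping.
#' @param scenario `"salt_endogenous_GG"` (GG only from intracellular
#'   synthesis; exchange closed for uptake) or `"exogenous_GG"` (exchange
#'   open for uptake).
#' @param ggps_rxn,glpk_rxn Reaction-id mapping passed to [gg_strains()].
#' @return A `strain_spec` object (list with `name`, `knockouts`, `scenario`).
#' @export
strain_spec <- function(name = c("WT", "dggpS", "dglpK", "dslr1670",
                                 "dglpK_dslr1670", "custom"),
                        knockouts = NULL,
                        scenario = c("salt_endogenous_GG", "exogenous_GG"),
                        ggps_rxn = "GGPS", glpk_rxn = "GLPK") {
  name <- match.arg(name)
  scenario <- match.arg(scenario)
  if (is.null(knockouts)) {
    if (name == "custom") stop("custom strain needs explicit knockouts")
    map <- gg_strains(ggps_rxn, glpk_rxn)
    knockouts <- map$knockouts[[match(name, map$strain)]]
  }
  structure(list(name = name, knockouts = unique(knockouts),
                 scenario = scenario),
            class = "strain_spec")
}

#' Apply a strain's constraints to a model
#'
#' Knocked-out reactions get `lower = upper = 0`; all other bounds are
#' untouched. Under the `exogenous_GG` scenario the GG exchange is opened
#' for uptake (lower bound -1000, or fixed to `-qGG` when a rate is given);
#' under `salt_endogenous_GG` it stays closed to uptake.
#'
#' @param model A [metabolic_model()] carrying the GG extension.
#' @param strain A [strain_spec()] or a strain name string.
#' @param qGG Optional GG uptake rate (mmol gDW^-1 h^-1) fixed as an
#'   equality on the exchange (exogenous scenario only).
#' @param gg_exchange Id of the GG exchange reaction.
#' @return The constrained [metabolic_model()].
#' @export
apply_strain <- function(model, strain, qGG = NULL,
                         gg_exchange = "EX_glcglyc(e)") {
  if (is.character(strain)) strain <- strain_spec(strain)
  stopifnot(inherits(strain, "strain_spec"))
  unknown <- setdiff(strain$knockouts, model$reactions$id)
  if (length(unknown)) {
    stop("unknown knockout reaction id(s): ", paste(unknown, collapse = ", "))
  }
  if (model$objective %in% strain$knockouts) {
    stop("cannot knock out the objective reaction: ", model$objective)
  }
  ko <- model$reactions$id %in% strain$knockouts
  model$reactions$lower_bound[ko] <- 0
  model$reactions$upper_bound[ko] <- 0
  if (strain$scenario == "exogenous_GG") {
    i <- match(gg_exchange, model$reactions$id)
    if (is.na(i)) stop("GG exchange reaction not in model: ", gg_exchange)
    if (is.null(qGG)) {
      model$reactions$lower_bound[i] <- -1000
    } else {
      stopifnot(qGG >= 0)
      model$reactions$lower_bound[i] <- -qGG
      model$reactions$upper_bound[i] <- -qGG
    }
  }
  model
}
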