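#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` bundles a metabolite table, a reaction table and the
#' id of the biomass (objective) reaction. It is the container every other
#' function in the package operates on.
#'
#' @param metabolites A data frame with columns `id`, `name`, `compartment`
#'   (`"c"`, `"p"` or `"e"`), and optionally `formula` (elemental formula
#'   string, e.g. `"C9H18O8"`) and `charge`.
#' @param reactions A data frame with columns `id`, `name`, `stoichiometry`
#'   (a list column of named numeric vectors, metabolite id -> signed
#'   coefficient, negative = consumed), `lower_bound`, `upper_bound`
#'   (mmol gDW^-1 h^-1), and optionally `gene_association`, `is_exchange`,
#'   `is_sink`. Missing bounds default to -1000/1000 (reversible) which is
#'   the convention of the BiGG model family; boundary flags are inferred
#'   from the stoichiometry when absent (a reaction touching exactly one
#'   metabolite is a boundary reaction; sinks drain cytosolic species).
#' @param objective Id of the objective (biomass) reaction.
#'
#' @return An object of class `metabolic_model`: a list with tibbles
#'   `metabolites` and `reactions` plus the `objective` id.
#' @examples
#' m <- metabolic_model(
#'   metabolites = tibble::tibble(
#'     id = c("a_c", "b_c"), name = c("A", "B"), compartment = "c"
#'   ),
#'   reactions = tibble::tibble(
#'     id = c("EX_a(e)", "AB", "DM_b"),
#'     name = c("A exchange", "A to B", "B drain"),
#'     stoichiometry = list(c(a_c = -1), c(a_c = -1, b_c = 1), c(b_c = -1)),
#'     lower_bound = c(-10, 0, 0), upper_bound = 1000
#'   ),
#'   objective = "DM_b"
#' )
#' solve_fba(m)$objective_value
#' @export
metabolic_model <- function(metabolites, reactions, objective) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (nrow(metabolites) == 0 && !"id" %in% names(metabolites)) {
    metabolites <- tibble::tibble(id = character(), name = character(),
                                  compartment = character())
  }
  if (nrow(reactions) == 0 && !"id" %in% names(reactions)) {
    reactions <- tibble::tibble(id = character(), name = character(),
                                stoichiometry = list(),
                                lower_bound = numeric(),
                                upper_bound = numeric())
  }
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  if (!"gene_association" %in% names(reactions)) {
    reactions$gene_association <- NA_character_
  }
  n_met_touched <- vapply(reactions$stoichiometry, length, integer(1))
  if (!"is_exchange" %in% names(reactions)) {
    reactions$is_exchange <- n_met_touched == 1L & grepl("^EX_", reactions$id)
  }
  if (!"is_sink" %in% names(reactions)) {
    reactions$is_sink <- n_met_touched == 1L & !reactions$is_exchange
  }
  # unset bounds: reversible -1000/1000 unless flagged otherwise
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -1000
  reactions$upper_bound[is.na(reactions$upper_bound)] <- 1000
  reactions <- reactions[, c(
    "id", "name", "stoichiometry", "lower_bound", "upper_bound",
    "gene_association", "is_exchange", "is_sink"
  )]

  model <- structure(
    list(metabolites = metabolites, reactions = reactions, objective = objective),
    class = "metabolic_model"
  )
  validate_metabolic_model(model)
  model
}

validate_metabolic_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  bad_cmp <- met$id[!is.na(met$compartment) &
                      !endsWith(met$id, paste0("_", met$compartment))]
  if (length(bad_cmp)) {
    stop("metabolite id/compartment mismatch: ", paste(bad_cmp, collapse = ", "))
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    stop("reaction with lower_bound > upper_bound: ",
         paste(rxn$id[rxn$lower_bound > rxn$upper_bound], collapse = ", "))
  }
  refs <- unique(unlist(lapply(rxn$stoichiometry, names)))
  missing <- setdiff(refs, met$id)
  if (length(missing)) {
    stop("reactions reference unknown metabolites: ",
         paste(missing, collapse = ", "))
  }
  boundary <- rxn$is_exchange | rxn$is_sink
  n_touched <- vapply(rxn$stoichiometry, length, integer(1))
  if (any(boundary & n_touched != 1L)) {
    stop("exchange/sink reaction touching more than one metabolite: ",
         paste(rxn$id[boundary & n_touched != 1L], collapse = ", "))
  }
  if (nrow(rxn) > 0 && !model$objective %in% rxn$id) {
    stop("objective reaction not in model: ", model$objective)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions; objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Build the sparse stoichiometric matrix S of a model
#'
#' Rows are metabolites, columns reactions; entry (m, r) is reaction r's
#' signed coefficient for metabolite m. Steady-state flux balance requires
#' `S %*% v == 0`.
#'
#' @param model A [metabolic_model()].
#' @return A sparse `dgCMatrix` with metabolite/reaction ids as dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (length(rxn_ids) == 0 || length(met_ids) == 0) {
    return(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(length(met_ids), length(rxn_ids)),
      dimnames = list(met_ids, rxn_ids)
    ))
  }
  ijx <- purrr::imap(model$reactions$stoichiometry, function(st, j) {
    list(i = match(names(st), met_ids), j = rep(j, length(st)), x = unname(st))
  })
  Matrix::sparseMatrix(
    i = unlist(lapply(ijx, `[[`, "i")),
    j = unlist(lapply(ijx, `[[`, "j")),
    x = unlist(lapply(ijx, `[[`, "x")),
    dims = c(length(met_ids), length(rxn_ids)),
    dimnames = list(met_ids, rxn_ids)
  )
}

#' Export the stoichiometric matrix as TSV for inspection
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stoich_tsv <- function(model, path) {
  S <- as.matrix(stoich_matrix(model))
  df <- data.frame(metabolite = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse an elemental formula string into atom counts
#'
#' @param formula Formula string such as `"C9H18O8"`; `NA` returns `NULL`.
#' @return Named numeric vector of atom counts, or `NULL` for missing input.
#' @examples
#' parse_formula("C9H18O8")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1 || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", formula))) {
    el <- gsub("[0-9]", "", toks)
    ct <- as.numeric(ifelse(gsub("[A-Za-z]", "", toks) == "", "1",
                            gsub("[A-Za-z]", "", toks)))
    out <- tapply(ct, el, sum)
    return(stats::setNames(as.numeric(out), names(out)))
  }
  stop("cannot parse formula: ", formula)
}

#' Check elemental balance of reactions
#'
#' Sums `coefficient x atom count` per chemical element for each requested
#' reaction. Internal reactions should balance exactly; exchange and sink
#' reactions touch a single metabolite and are unbalanced by construction,
#' which is reported as status `"boundary"` rather than as an imbalance.
#' A participating metabolite without a formula yields status `"unknown"`
#' (never a silent zero).
#'
#' @param model A [metabolic_model()].
#' @param reaction_ids Reactions to check; default all.
#' @return A tibble with one row per reaction and element: columns
#'   `reaction_id`, `element`, `net`, `status` (`"balanced"`, `"unbalanced"`,
#'   `"boundary"`, `"unknown"`). Boundary/unknown reactions get a single row
#'   with `element = NA`.
#' @examples
#' tm <- toy_model()
#' element_balance(tm, "GLCGLYCHyd")
#' @export
element_balance <- function(model, reaction_ids = NULL) {
  rxn <- model$reactions
  if (!is.null(reaction_ids)) {
    missing <- setdiff(reaction_ids, rxn$id)
    if (length(missing)) stop("unknown reaction id(s): ",
                              paste(missing, collapse = ", "))
    rxn <- rxn[match(reaction_ids, rxn$id), ]
  }
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  rows <- purrr::pmap(
    list(rxn$id, rxn$stoichiometry, rxn$is_exchange | rxn$is_sink),
    function(id, st, boundary) {
      if (boundary) {
        return(tibble::tibble(reaction_id = id, element = NA_character_,
                              net = NA_real_, status = "boundary"))
      }
      fs <- formulas[names(st)]
      if (anyNA(fs)) {
        return(tibble::tibble(reaction_id = id, element = NA_character_,
                              net = NA_real_, status = "unknown"))
      }
      atom_lists <- lapply(fs, parse_formula)
      elements <- sort(unique(unlist(lapply(atom_lists, names))))
      net <- vapply(elements, function(el) {
        sum(vapply(seq_along(st), function(i) {
          st[[i]] * (atom_lists[[i]][el] %||% 0)
        }, numeric(1)))
      }, numeric(1))
      status <- if (all(abs(net) < 1e-9)) "balanced" else "unbalanced"
      tibble::tibble(reaction_id = id, element = elements,
                     net = unname(net), status = status)
    }
  )
  dplyr::bind_rows(rows)
}

#' Is a reaction elementally balanced?
#'
#' @inheritParams element_balance
#' @param reaction_id A single reaction id.
#' @return `TRUE`, `FALSE`, or `NA` when the balance is unknown or the
#'   reaction is a boundary reaction.
#' @export
is_balanced <- function(model, reaction_id) {
  bal <- element_balance(model, reaction_id)
  st <- unique(bal$status)
  if (st %in% c("boundary", "unknown")) return(NA)
  st == "balanced"
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Bundled elemental formulas for the GG pathway metabolites
#'
#' Formula annotations applied when a source model lacks them, covering the
#' species that the glucosylglycerol extension introduces or touches.
#'
#' @return A tibble with columns `stem` (metabolite id without compartment
#'   suffix) and `formula`.
#' @export
gg_formula_table <- function() {
  tibble::tibble(
    stem = c("glcglyc", "glyc", "glc__D", "g1p", "g6p", "h2o", "pi",
             "co2", "ch2o", "glyc3p"),
    formula = c("C9H18O8", "C3H8O3", "C6H12O6", "C6H11O9P", "C6H11O9P",
                "H2O", "HO4P", "CO2", "CH2O", "C3H7O6P")
  )
}

# split "glcglyc_c" -> stem "glcglyc", compartment "c"
split_met_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)_([cpe])$", id))[[1]]
  if (length(m) != 3) return(list(stem = id, compartment = NA_character_))
  list(stem = m[2], compartment = m[3])
}
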