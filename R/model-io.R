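# Model serialization: BiGG-style JSON (native) and SBML Level 3 + fbc.
#
# Ids are stored internally in canonical BiGG form ("EX_glcglyc(e)",
# "glc__D_c"); SBML escaping (R_/M_ prefixes, _DASH_, _LPAREN_, _RPAREN_)
# is applied only at serialization and undone on read.

#' Convert between SBML-escaped and canonical BiGG identifiers
#'
#' SBML forbids characters like `(`, `)` and `-` in ids, so BiGG-derived
#' models escape them (`R_EX_GLCGLYC_LPAREN_e_RPAREN`). `unescape_sbml_id()`
#' strips the `R_`/`M_` prefix and restores the canonical spelling;
#' `escape_sbml_id()` is its inverse. Exchange reaction stems written in
#' upper case by some exports are folded to the lower-case BiGG metabolite
#' spelling.
#'
#' @param id Identifier string.
#' @param prefix `"R"` for reactions, `"M"` for metabolites (escape only).
#' @return The converted identifier.
#' @examples
#' unescape_sbml_id("R_EX_GLCGLYC_LPAREN_e_RPAREN") # "EX_glcglyc(e)"
#' escape_sbml_id("EX_glcglyc(e)", "R")
#' @export
unescape_sbml_id <- function(id) {
  out <- sub("^[RMS]_", "", id)
  out <- gsub("_DASH_", "__", out, fixed = TRUE)
  out <- gsub("_LPAREN_", "(", out, fixed = TRUE)
  out <- gsub("_RPAREN_", ")", out, fixed = TRUE)
  out <- sub("_LPAREN$", "(", out)
  out <- sub("_RPAREN$", ")", out)
  out <- sub("_$", "", out)
  # fold upper-cased exchange stems to BiGG's lower-case metabolite spelling
  ex <- grepl("^EX_", out)
  stem <- sub("^EX_", "", sub("\\(.*$", "", out[ex]))
  allcaps <- stem == toupper(stem) & grepl("[A-Z]", stem)
  out[ex][allcaps] <- sub("^EX_[^(]*", paste0("EX_", tolower(stem[allcaps])),
                          out[ex][allcaps])
  out
}

#' @rdname unescape_sbml_id
#' @export
escape_sbml_id <- function(id, prefix = c("R", "M")) {
  prefix <- match.arg(prefix)
  out <- gsub("(", "_LPAREN_", id, fixed = TRUE)
  out <- gsub(")", "_RPAREN_", out, fixed = TRUE)
  out <- sub("_$", "", out) # trailing ")" escapes without a trailing "_"
  paste0(prefix, "_", out)
}

#' Read a stoichiometric model from file
#'
#' Supports the two dialects used by the Synechocystis reconstruction
#' family: BiGG-style JSON (the package's native format) and SBML Level 3
#' with the fbc extension. All reactions, bounds, formulas (when present)
#' and the objective are preserved; SBML-escaped ids are normalised to
#' canonical BiGG form.
#'
#' @param source Path to a model file, or a single string containing the
#'   document itself.
#' @param dialect `"bigg-json"` or `"sbml-fbc"`; default guesses from the
#'   file extension / content.
#' @return A [metabolic_model()].
#' @seealso [write_metabolic_model()]
#' @export
read_metabolic_model <- function(source, dialect = c("auto", "bigg-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  is_path <- length(source) == 1 && !grepl("[{<\n]", source) && file.exists(source)
  txt <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else source
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*\\{", txt)) "bigg-json" else "sbml-fbc"
  }
  switch(dialect,
    "bigg-json" = read_model_json(txt),
    "sbml-fbc" = read_model_sbml(txt)
  )
}

#' Write a stoichiometric model to file
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @param dialect `"bigg-json"` or `"sbml-fbc"`; default guesses from the
#'   extension (`.xml`/`.sbml` give SBML).
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path,
                                  dialect = c("auto", "bigg-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else {
      "bigg-json"
    }
  }
  switch(dialect,
    "bigg-json" = write_model_json(model, path),
    "sbml-fbc" = write_model_sbml(model, path)
  )
  invisible(path)
}

# --- BiGG-style JSON ---------------------------------------------------------

read_model_json <- function(txt) {
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyDataFrame = FALSE, simplifyVector = FALSE),
    error = function(e) stop("malformed BiGG JSON: ", conditionMessage(e))
  )
  mets <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% split_met_id(m$id)$compartment,
      formula = m$formula %||% NA_character_,
      charge = as.integer(m$charge %||% NA_integer_)
    )
  }))
  rxns <- dplyr::bind_rows(lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    tibble::tibble(
      id = r$id,
      name = r$name %||% r$id,
      stoichiometry = list(st),
      lower_bound = json_bound(r$lower_bound, -1000),
      upper_bound = json_bound(r$upper_bound, 1000),
      gene_association = r$gene_reaction_rule %||% NA_character_,
      is_exchange = isTRUE(r$is_exchange) ||
        (length(st) == 1L && grepl("^EX_", r$id)),
      is_sink = isTRUE(r$is_sink) ||
        (length(st) == 1L && !grepl("^EX_", r$id))
    )
  }))
  objective <- doc$objective %||% {
    obj_coef <- vapply(doc$reactions,
                       function(r) as.numeric(r$objective_coefficient %||% 0),
                       numeric(1))
    if (length(obj_coef) && !any(obj_coef != 0)) {
      stop("model has no objective reaction")
    }
    if (length(obj_coef)) rxns$id[which(obj_coef != 0)[1]] else NA_character_
  }
  if (nrow(mets) == 0) {
    mets <- tibble::tibble(id = character(), name = character(),
                           compartment = character())
  }
  metabolic_model(mets, rxns, objective)
}

# null -> Inf convention for the unbounded storage sink
json_bound <- function(x, default) {
  if (is.null(x)) return(default)
  if (identical(x, "inf") || identical(x, "Inf")) return(Inf)
  if (identical(x, "-inf") || identical(x, "-Inf")) return(-Inf)
  as.numeric(x)
}

write_model_json <- function(model, path) {
  mets <- purrr::pmap(model$metabolites, function(id, name, compartment,
                                                  formula, charge) {
    out <- list(id = id, name = name, compartment = compartment)
    if (!is.na(formula)) out$formula <- formula
    if (!is.na(charge)) out$charge <- charge
    out
  })
  rxns <- purrr::pmap(model$reactions, function(id, name, stoichiometry,
                                                lower_bound, upper_bound,
                                                gene_association, is_exchange,
                                                is_sink) {
    out <- list(
      id = id, name = name,
      metabolites = as.list(stoichiometry),
      lower_bound = if (is.finite(lower_bound)) lower_bound else
        paste0(if (lower_bound < 0) "-" else "", "inf"),
      upper_bound = if (is.finite(upper_bound)) upper_bound else
        paste0(if (upper_bound < 0) "-" else "", "inf"),
      objective_coefficient = if (id == model$objective) 1 else 0
    )
    if (!is.na(gene_association)) out$gene_reaction_rule <- gene_association
    out$is_exchange <- is_exchange
    out$is_sink <- is_sink
    out
  })
  doc <- list(metabolites = mets, reactions = rxns, objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# --- SBML Level 3 + fbc ------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xattr <- function(node, name) {
  a <- xml2::xml_attrs(node) # names come back with ns prefixes stripped
  if (name %in% names(a)) a[[name]] else NA_character_
}

read_model_sbml <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("malformed SBML: no <model>")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- dplyr::bind_rows(lapply(sp, function(node) {
    sid <- xml2::xml_attr(node, "id")
    tibble::tibble(
      id = unescape_sbml_id(sid),
      name = xml2::xml_attr(node, "name") %||% unescape_sbml_id(sid),
      compartment = xml2::xml_attr(node, "compartment"),
      formula = xattr(node, "chemicalFormula"),
      charge = as.integer(xattr(node, "charge"))
    )
  }))

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    vapply(params, function(p) sbml_value(xml2::xml_attr(p, "value")), numeric(1)),
    vapply(params, function(p) xml2::xml_attr(p, "id"), character(1))
  )

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) && !length(sp)) stop("malformed SBML: reactions without species")
  rxns <- dplyr::bind_rows(lapply(rx, function(node) {
    rid_raw <- xml2::xml_attr(node, "id")
    sref <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (!length(refs)) return(numeric(0))
      stats::setNames(
        sign * vapply(refs, function(r) {
          as.numeric(xml2::xml_attr(r, "stoichiometry") %||% 1)
        }, numeric(1)),
        unescape_sbml_id(vapply(refs, function(r) xml2::xml_attr(r, "species"),
                                character(1)))
      )
    }
    st_neg <- sref(".//s:listOfReactants/s:speciesReference", -1)
    st_pos <- sref(".//s:listOfProducts/s:speciesReference", 1)
    st <- c(st_neg, st_pos)
    st <- tapply(st, names(st), sum)[unique(names(c(st_neg, st_pos)))]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xattr(node, "lowerFluxBound")
    ub_ref <- xattr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    ga_node <- xml2::xml_find_first(
      node, ".//fbc:geneProductAssociation//fbc:geneProductRef", ns)
    ga <- if (inherits(ga_node, "xml_missing")) NA_character_ else
      xattr(ga_node, "geneProduct")
    id <- unescape_sbml_id(rid_raw)
    tibble::tibble(
      id = id, name = xml2::xml_attr(node, "name") %||% id,
      stoichiometry = list(stats::setNames(as.numeric(st), names(st))),
      lower_bound = lb, upper_bound = ub,
      gene_association = ga,
      is_exchange = length(st) == 1L && grepl("^EX_", id),
      is_sink = length(st) == 1L && !grepl("^EX_", id)
    )
  }))

  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop("SBML model has no fbc objective")
  }
  objective <- unescape_sbml_id(xml2::xml_attr(obj_ref, "reaction"))
  metabolic_model(mets, rxns, objective)
}

sbml_value <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (x %in% c("INF", "inf")) return(Inf)
  if (x %in% c("-INF", "-inf")) return(-Inf)
  as.numeric(x)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0(
      '<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
      'fbc:required="false">'), SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>',
            sort(unique(model$metabolites$compartment))),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  met_lines <- purrr::pmap_chr(
    model$metabolites,
    function(id, name, compartment, formula, charge) {
      extra <- ""
      if (!is.na(formula)) {
        extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', formula))
      }
      if (!is.na(charge)) {
        extra <- paste0(extra, sprintf(' fbc:charge="%d"', charge))
      }
      sprintf(paste0('      <species id="%s" name="%s" compartment="%s"',
                     ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                     ' constant="false"%s/>'),
              escape_sbml_id(id, "M"), esc(name), compartment, extra)
    }
  )
  fmt_b <- function(x) {
    if (is.infinite(x)) paste0(if (x < 0) "-" else "", "INF") else format(x)
  }
  par_lines <- purrr::pmap_chr(
    model$reactions[, c("id", "lower_bound", "upper_bound")],
    function(id, lower_bound, upper_bound) {
      rid <- escape_sbml_id(id, "R")
      paste0(
        sprintf(paste0('      <parameter id="lb_%s" value="%s" constant="true"',
                       '/>\n'), rid, fmt_b(lower_bound)),
        sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
                rid, fmt_b(upper_bound))
      )
    }
  )
  rxn_lines <- purrr::pmap_chr(
    model$reactions,
    function(id, name, stoichiometry, lower_bound, upper_bound,
             gene_association, is_exchange, is_sink) {
      rid <- escape_sbml_id(id, "R")
      sides <- function(coefs, tag) {
        if (!length(coefs)) return(character(0))
        c(sprintf("        <listOf%s>", tag),
          sprintf(paste0('          <speciesReference species="%s" ',
                         'stoichiometry="%s" constant="true"/>'),
                  escape_sbml_id(names(coefs), "M"), format(abs(coefs))),
          sprintf("        </listOf%s>", tag))
      }
      ga_lines <- if (!is.na(gene_association)) {
        c("        <fbc:geneProductAssociation>",
          sprintf('          <fbc:geneProductRef fbc:geneProduct="%s"/>',
                  gene_association),
          "        </fbc:geneProductAssociation>")
      } else {
        character(0)
      }
      paste(c(
        sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                       'fast="false" fbc:lowerFluxBound="lb_%s" ',
                       'fbc:upperFluxBound="ub_%s">'),
                rid, esc(name), tolower(lower_bound < 0), rid, rid),
        ga_lines,
        sides(stoichiometry[stoichiometry < 0], "Reactants"),
        sides(stoichiometry[stoichiometry > 0], "Products"),
        "      </reaction>"
      ), collapse = "\n")
    }
  )
  genes <- unique(stats::na.omit(model$reactions$gene_association))
  gene_block <- if (length(genes)) {
    c("    <fbc:listOfGeneProducts>",
      sprintf(paste0('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>'),
              genes, genes),
      "    </fbc:listOfGeneProducts>")
  } else {
    character(0)
  }
  lines <- c(
    lines, met_lines,
    "    </listOfSpecies>",
    "    <listOfParameters>", par_lines, "    </listOfParameters>",
    "    <listOfReactions>", rxn_lines, "    </listOfReactions>",
    gene_block,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'),
            escape_sbml_id(model$objective, "R")),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>"
  )
  writeLines(lines, path)
}
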