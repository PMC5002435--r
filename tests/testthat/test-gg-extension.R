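test_that("extension adds exactly the seven salvage reactions, idempotently", {
  base <- toy_model(extended = FALSE)
  ext <- extend_with_gg(base)
  added <- setdiff(ext$reactions$id, base$reactions$id)
  expect_length(added, 7)
  expect_setequal(added, gg_extension_specs()$id)
  # idempotence: a second application is a no-op
  ext2 <- extend_with_gg(ext)
  expect_equal(ext2$reactions$id, ext$reactions$id)
  expect_equal(ext2$reactions$lower_bound, ext$reactions$lower_bound)
})

test_that("cleavage stoichiometries match the published reaction equations", {
  S <- stoich_matrix(toy_model())
  phos <- S[, "GLCGLYCPhosphorylase"]
  expect_equal(phos[phos != 0],
               c(glcglyc_c = -1, g1p_c = 1, glyc_c = 1, pi_c = -1)[
                 names(phos[phos != 0])])
  hyd <- S[, "GLCGLYCHyd"]
  expect_equal(sum(hyd != 0), 4)
  # both cleavages are slr1670-associated; storage and leakage have no gene
  rxns <- toy_model()$reactions
  expect_equal(
    rxns$gene_association[match(c("GLCGLYCHyd", "GLCGLYCPhosphorylase"),
                                rxns$id)],
    c("slr1670", "slr1670")
  )
  expect_true(all(is.na(
    rxns$gene_association[match(c("GLCGLYCstorage", "glcglyctpp"), rxns$id)]
  )))
  # irreversible "=>" reactions have zero lower bounds; storage is unbounded
  specs <- gg_extension_specs()
  irr <- setdiff(specs$id, "GLCGLYCtex")
  expect_true(all(specs$lower_bound[specs$id %in% irr] == 0))
  expect_identical(specs$upper_bound[specs$id == "GLCGLYCstorage"], Inf)
})

test_that("missing metabolites are created from the formula table, unknown ones error", {
  mets <- tibble::tibble(
    id = c("h2o_c", "pi_c", "glc__D_c", "g1p_c"),
    name = c("water", "pi", "glucose", "g1p"), compartment = "c",
    formula = c("H2O", "HO4P", "C6H12O6", "C6H11O9P")
  )
  rxns <- tibble::tibble(
    id = "DM_glc", name = "demand", stoichiometry = list(c(glc__D_c = -1)),
    lower_bound = 0, upper_bound = 1000, is_exchange = FALSE, is_sink = TRUE
  )
  tiny <- metabolic_model(mets, rxns, "DM_glc")
  ext <- extend_with_gg(tiny)
  created <- setdiff(ext$metabolites$id, tiny$metabolites$id)
  expect_setequal(created, c("glcglyc_c", "glcglyc_p", "glcglyc_e", "glyc_c"))
  i <- match("glcglyc_c", ext$metabolites$id)
  expect_equal(ext$metabolites$formula[i], "C9H18O8")

  bad_spec <- gg_extension_specs()[1, ]
  bad_spec$stoichiometry <- list(c(mystery_c = -1))
  bad_spec$id <- "EX_mystery"
  expect_error(extend_with_gg(tiny, bad_spec), "mystery")
})

test_that("strain constraints silence the right reactions and only those", {
  tm <- toy_model()
  mut <- apply_strain(tm, strain_spec("dslr1670"))
  i <- match(c("GLCGLYCHyd", "GLCGLYCPhosphorylase"), mut$reactions$id)
  expect_equal(mut$reactions$lower_bound[i], c(0, 0))
  expect_equal(mut$reactions$upper_bound[i], c(0, 0))
  untouched <- setdiff(seq_len(nrow(tm$reactions)), i)
  expect_equal(mut$reactions$lower_bound[untouched],
               tm$reactions$lower_bound[untouched])
  expect_equal(mut$reactions$upper_bound[untouched],
               tm$reactions$upper_bound[untouched])
  # FBA flux through knocked-out reactions is exactly zero
  res <- solve_fba(mut)
  expect_equal(unname(res$fluxes[c("GLCGLYCHyd", "GLCGLYCPhosphorylase")]),
               c(0, 0))

  # WT with empty knockout set leaves the model unchanged
  wt <- apply_strain(tm, strain_spec("WT"))
  expect_equal(wt$reactions, tm$reactions)

  expect_error(apply_strain(tm, strain_spec("custom", knockouts = "NOPE")),
               "unknown knockout")
  expect_error(apply_strain(tm, strain_spec("custom", knockouts = "BIOMASS")),
               "objective")
})

test_that("double mutant is the union of the single mutants", {
  strains <- gg_strains()
  ko <- function(s) strains$knockouts[[match(s, strains$strain)]]
  expect_setequal(ko("dglpK_dslr1670"), union(ko("dglpK"), ko("dslr1670")))
  expect_true(all(c("GLCGLYCHyd", "GLCGLYCPhosphorylase") %in% ko("dslr1670")))
})

test_that("without a GG source the synthesis mutant exports no glycerol", {
  tm <- toy_model()
  mut <- apply_strain(tm, strain_spec("dggpS", scenario = "salt_endogenous_GG"))
  res <- solve_fba(mut)
  expect_equal(res$status, "optimal")
  expect_equal(unname(res$fluxes["EX_glyc(e)"]), 0)
})

test_that("knockout order does not matter for disjoint sets", {
  tm <- toy_model()
  a <- apply_strain(apply_strain(tm, strain_spec("dglpK")),
                    strain_spec("dggpS"))
  b <- apply_strain(apply_strain(tm, strain_spec("dggpS")),
                    strain_spec("dglpK"))
  expect_equal(a$reactions, b$reactions)
})

test_that("adding a zero-bounded reaction never changes BOFmax", {
  tm <- toy_model()
  before <- solve_fba(tm)$objective_value
  spec <- tibble::tibble(
    id = "NULLRXN", name = "pinned reaction",
    stoichiometry = list(c(glyc_c = -1, glc__D_c = 1)),
    lower_bound = 0, upper_bound = 0, gene_association = NA_character_,
    is_exchange = FALSE, is_sink = FALSE, add_if_absent = TRUE
  )
  tm2 <- extend_with_gg(tm, spec)
  expect_equal(solve_fba(tm2)$objective_value, before, tolerance = 1e-9)

  set.seed(77)
  for (i in 1:5) {
    rm <- random_small_model(sample(5:9, 1), sample(3:5, 1))
    v0 <- solve_fba(rm$model)
    if (v0$status != "optimal") next
    m2 <- rm$model
    m2$reactions <- dplyr::bind_rows(
      m2$reactions,
      tibble::tibble(
        id = "pinned", name = "pinned",
        stoichiometry = list(stats::setNames(1, m2$metabolites$id[1])),
        lower_bound = 0, upper_bound = 0,
        gene_association = NA_character_,
        is_exchange = FALSE, is_sink = TRUE
      )
    )
    expect_equal(solve_fba(m2)$objective_value, v0$objective_value,
                 tolerance = 1e-9)
  }
})

test_that("exogenous scenario opens GG uptake, endogenous keeps it closed", {
  tm <- toy_model()
  exo <- apply_strain(tm, strain_spec("WT", scenario = "exogenous_GG"))
  i <- match("EX_glcglyc(e)", exo$reactions$id)
  expect_lt(exo$reactions$lower_bound[i], 0)
  endo <- apply_strain(tm, strain_spec("WT", scenario = "salt_endogenous_GG"))
  expect_equal(endo$reactions$lower_bound[i], 0)
  fixed <- apply_strain(tm, strain_spec("dggpS", scenario = "exogenous_GG"),
                        qGG = 0.01)
  expect_equal(fixed$reactions$lower_bound[i], -0.01)
  expect_equal(fixed$reactions$upper_bound[i], -0.01)
})
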