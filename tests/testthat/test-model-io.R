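test_that("model construction enforces the container invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$metabolites), 3)
  expect_equal(nrow(m$reactions), 3)
  expect_true(m$reactions$exchange[m$reactions$id == "EX_glc"])
  expect_false(m$reactions$exchange[m$reactions$id == "T"])

  # duplicate reaction id
  expect_error(metabolic_model(
    mets_ec("a_c"),
    list(list(id = "R", stoich = c(a_c = 1), lb = 0, ub = 1),
         list(id = "R", stoich = c(a_c = -1), lb = 0, ub = 1))),
    "duplicate reaction id.*R")
  # undeclared metabolite
  expect_error(metabolic_model(
    mets_ec("a_c"),
    list(list(id = "R", stoich = c(zz_c = 1), lb = 0, ub = 1))),
    "undeclared metabolite.*zz_c")
  # empty model
  expect_error(metabolic_model(mets_ec("a_c"), list()), "no reactions")
  # zero coefficient
  expect_error(metabolic_model(
    mets_ec("a_c", "b_c"),
    list(list(id = "R", stoich = c(a_c = -1, b_c = 0), lb = 0, ub = 1))),
    "zero coefficient")
  # irreversible with negative lb
  expect_error(metabolic_model(
    mets_ec("a_c", "b_c"),
    list(list(id = "R", stoich = c(a_c = -1, b_c = 1), lb = -2, ub = 1))),
    "negative lower bound")
  # objective must be exactly one of metabolite/reaction
  expect_error(metabolic_model(
    mets_ec("a_c", "b_c"),
    list(list(id = "R", stoich = c(a_c = -1, b_c = 1), lb = 0, ub = 1)),
    objective = list(metabolite = "a_c", reaction = "R")),
    "exactly one")
})

test_that("compartment tags are stripped in both dialects", {
  m <- metabolic_model(
    data.frame(id = c("glc[c]", "pyr_c", "glc[e]"),
               compartment = c("c", "c", "e")),
    list(list(id = "R", stoich = stats::setNames(c(-1, 1), c("glc[c]", "pyr_c")),
              lb = 0, ub = 1)))
  expect_equal(m$metabolites$base_id, c("glc", "pyr", "glc"))
})

test_that("tabular JSON and TSV round trips reproduce the model field-by-field", {
  m <- make_toy_liver_model()
  jf <- tempfile(fileext = ".json")
  write_model_json(m, jf)
  m2 <- read_model_json(jf)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$reactions, m$reactions)
  expect_equal(as.matrix(m2$stoich), as.matrix(m$stoich))
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$objective, m$objective)
  expect_equal(m2$compartments, m$compartments)

  stem <- tempfile()
  write_model_tsv(m, stem)
  m3 <- read_model_tsv(stem)
  expect_equal(m3$reactions, m$reactions)
  expect_equal(as.matrix(m3$stoich), as.matrix(m$stoich))
  expect_equal(m3$genes, m$genes)
  expect_equal(m3$objective, m$objective)
})

test_that("apply_medium closes unlisted uptakes and applies secretion pairs", {
  m <- two_route_model()
  med <- medium_spec(uptake = c(EX_s = 10))
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_s"], -10)

  # unlisted uptakes are closed
  m3 <- apply_medium(m, medium_spec())
  expect_equal(m3$reactions$lb[m3$reactions$id == "EX_s"], 0)
  # and the objective optimum collapses to zero
  ts <- solve_two_stage(split_reversible(m3))
  expect_equal(ts$z_star, 0, tolerance = 1e-9)

  # a forced-secretion pair lands as (lb, ub) on the forward column
  mb <- metabolic_model(
    mets_ec("bil_e", "bil_c", "s_e", "s_c", "atp_c"),
    list(
      list(id = "EX_s", stoich = c(s_e = -1), lb = -100, ub = 0, reversible = TRUE),
      list(id = "T", stoich = c(s_e = -1, s_c = 1), lb = 0, ub = 100),
      list(id = "CONV", stoich = c(s_c = -1, atp_c = 1, bil_c = 1), lb = 0, ub = 100),
      list(id = "Tb", stoich = c(bil_c = -1, bil_e = 1), lb = 0, ub = 100),
      list(id = "EX_bil", stoich = c(bil_e = -1), lb = 0, ub = 100)),
    objective = list(metabolite = "atp_c"))
  mb2 <- apply_medium(mb, medium_spec(uptake = c(EX_s = 10),
                                      secretion = list(EX_bil = c(1.7, 8.55))))
  k <- match("EX_bil", mb2$reactions$id)
  expect_equal(mb2$reactions$lb[k], 1.7)
  expect_equal(mb2$reactions$ub[k], 8.55)
  sys <- split_reversible(mb2)
  ex_f <- match("EX_bil_f", sys$cols$col_id)
  expect_equal(sys$cols$lb[ex_f], 1.7)
  expect_equal(sys$cols$ub[ex_f], 8.55)

  # unknown exchange id errors with the offending name
  expect_error(apply_medium(m, medium_spec(uptake = c(EX_missing = 5))),
               "EX_missing")
})

test_that("medium TSV reader distinguishes uptake and secretion rows", {
  med <- read_medium_tsv(extdata("medium_bilirubin_example.tsv"))
  expect_equal(unname(med$uptake["EX_glc"]), 10)
  expect_equal(med$secretion[["EX_bilirubin_direct"]], c(1.7, 8.55))
  expect_equal(med$secretion[["EX_bilirubin_indirect"]], c(0, 6.84))
})

test_that("reversible splitting maps bounds and negates stoichiometry", {
  m <- metabolic_model(
    mets_ec("a_c", "b_c"),
    list(list(id = "IR", stoich = c(a_c = -1, b_c = 1), lb = 0, ub = 5),
         list(id = "RV", stoich = c(a_c = -1, b_c = 1), lb = -3, ub = 5,
              reversible = TRUE),
         list(id = "SRC", stoich = c(a_c = 1), lb = 0, ub = 10),
         list(id = "SNK", stoich = c(b_c = -1), lb = 0, ub = 10)),
    objective = list(reaction = "SNK"))
  sys <- split_reversible(m)
  # R + r columns: 4 reactions, 1 reversible
  expect_equal(ncol(sys$S), 5)
  expect_equal(unname(sys$cols$lb[sys$cols$col_id == "IR_f"]), 0)
  expect_equal(unname(sys$cols$ub[sys$cols$col_id == "IR_f"]), 5)
  expect_equal(unname(sys$cols$ub[sys$cols$col_id == "RV_f"]), 5)
  expect_equal(unname(sys$cols$ub[sys$cols$col_id == "RV_b"]), 3)
  expect_equal(as.numeric(sys$S[, "RV_b"]), -as.numeric(sys$S[, "RV_f"]))
  # contradictory bounds error
  expect_error(metabolic_model(
    mets_ec("a_c", "b_c"),
    list(list(id = "BAD", stoich = c(a_c = -1, b_c = 1), lb = 3, ub = -1,
              reversible = TRUE))), "lb > ub")
})

test_that("net fluxes reconstructed from any split vector satisfy the original balance", {
  m <- make_toy_liver_model()
  sys <- split_reversible(m)
  set.seed(42)
  for (k in 1:5) {
    v <- runif(ncol(sys$S), 0, 5)
    lhs_split <- as.vector(sys$S %*% v)
    vnet <- net_fluxes(sys, stats::setNames(v, sys$cols$col_id))
    lhs_net <- as.vector(sys$model$stoich %*% vnet[colnames(sys$model$stoich)])
    expect_equal(lhs_split, lhs_net, tolerance = 1e-12)
  }
})

test_that("gene lookup returns all labelled reactions in model order", {
  m <- make_toy_liver_model()
  expect_equal(gene_to_reactions(m, "Ddc"),
               c("DDC_dopa", "DDC_htp", "DDC_trp"))
  expect_equal(gene_to_reactions(m, "NotAGene"), character(0))
  expect_true("Ddc" %in% model_genes(m))
})
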