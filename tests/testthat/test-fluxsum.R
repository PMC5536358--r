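test_that("production rate evaluates the literal compartment sum", {
  # met produced in c by R1 (coeff +1, v_f = 2) and consumed in m by R2
  # (coeff -1, v_b = 1): rate = 2 + 1 = 3
  m <- metabolic_model(
    data.frame(id = c("x_c", "x_m", "p_c", "q_m"),
               compartment = c("c", "m", "c", "m")),
    list(
      list(id = "R1", stoich = c(p_c = -1, x_c = 1), lb = 0, ub = 10),
      list(id = "R2", stoich = c(x_m = -1, q_m = 1), lb = -10, ub = 10,
           reversible = TRUE),
      list(id = "SRCp", stoich = c(p_c = 1), lb = 0, ub = 10),
      list(id = "Tx", stoich = c(x_c = -1, x_m = 1), lb = -10, ub = 10,
           reversible = TRUE),
      list(id = "SNKq", stoich = c(q_m = -1), lb = -10, ub = 10,
           reversible = TRUE)),
    objective = list(reaction = "SNKq"), boundary_compartment = "e")
  sys <- split_reversible(m)
  v <- stats::setNames(rep(0, ncol(sys$S)), sys$cols$col_id)
  v["R1_f"] <- 2; v["R2_b"] <- 1
  # hand-assembled state (not solver output) for the arithmetic check
  st <- structure(list(v = v, z = 0, sq_norm = sum(v^2), status = "optimal"),
                  class = "flux_state")
  expect_equal(production_rate(sys, st, "x"), 3)
  # all incident fluxes zero -> 0
  expect_equal(production_rate(sys, st, "q"), 0)
  expect_error(production_rate(sys, st, "nope"), "unknown metabolite")
})

test_that("boundary-only metabolites are rejected with advice", {
  m <- chain_model()
  sys <- split_reversible(m)
  ts <- solve_two_stage(sys)
  expect_error(production_rate(sys, ts$state, "glc_e"), "unknown")
  # base id 'glc' exists in both e and c; only c is counted
  expect_equal(production_rate(sys, ts$state, "glc"), 10, tolerance = 1e-8)
})

test_that("production rates match the brute-force loop on solved systems", {
  for (seed in c(4, 8, 15)) {
    m <- make_random_balanced_system(n_mets = 7, n_rxns = 11, seed = seed)
    sys <- split_reversible(m)
    ts <- solve_two_stage(sys)
    expect_identical(ts$state$status, "optimal")
    base_ids <- unique(m$metabolites$base_id[m$metabolites$compartment != "e"])
    for (b in base_ids) {
      expect_equal(production_rate(sys, ts$state, b),
                   brute_production_rate(sys, ts$state, b),
                   tolerance = 1e-9)
    }
  }
  # and on the toy hepatocyte under dysregulation
  mt <- make_toy_liver_model()
  cache <- run_normal_state(mt, genes = "Ddc")
  res <- run_gene(cache, "Ddc", mode = "up", delta = 1)
  for (b in c("lac", "pyr", "gln", "glu", "atp")) {
    expect_equal(production_rate(cache$system, res$deficient, b),
                 brute_production_rate(cache$system, res$deficient, b),
                 tolerance = 1e-9)
  }
})

test_that("fold change implements the epsilon policy", {
  expect_equal(fold_change(4, 2)[c("fc", "lfc")], list(fc = 2, lfc = 1))
  expect_equal(fold_change(2, 2)[c("fc", "lfc")], list(fc = 1, lfc = 0))
  nc <- fold_change(0, 0)
  expect_identical(nc$status, "no_change")
  expect_true(is.na(nc$fc) && is.na(nc$lfc))
  sat <- fold_change(3, 0)
  expect_identical(sat$status, "saturated")
  expect_true(is.finite(sat$lfc) && sat$lfc > 0)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("sign of change respects the no-change band", {
  expect_equal(sign_of_change(1.65), 1)
  expect_equal(sign_of_change(-0.69), -1)
  expect_equal(sign_of_change(0), 0)
  expect_equal(sign_of_change(NA_real_), 0)
  expect_equal(sign_of_change(1e-8), 0)
})

test_that("swapping the states negates every defined log fold change", {
  m <- make_toy_liver_model()
  cache <- run_normal_state(m, genes = "Ddc")
  res <- run_gene(cache, "Ddc", mode = "up", delta = 1)
  ids <- c("lac", "gln", "glu", "atp", "pyr")
  fwd <- production_profile(cache$system, cache$normal, res$deficient, ids)
  bwd <- production_profile(cache$system, res$deficient, cache$normal, ids)
  ok <- !is.na(fwd$lfc) & !is.na(bwd$lfc) & fwd$status == "ok"
  expect_true(any(ok))
  expect_equal(fwd$lfc[ok], -bwd$lfc[ok], tolerance = 1e-9)
})

test_that("fold changes and signs are invariant to a global flux rescaling", {
  m <- make_toy_liver_model()
  cache <- run_normal_state(m, genes = "Ddc")
  res <- run_gene(cache, "Ddc", mode = "up", delta = 1)
  ids <- c("lac", "gln", "glu", "pyr")
  p1 <- production_profile(cache$system, cache$normal, res$deficient, ids)
  scale_state <- function(st, lam) { st$v <- st$v * lam; st }
  p2 <- production_profile(cache$system, scale_state(cache$normal, 3.7),
                           scale_state(res$deficient, 3.7), ids)
  ok <- p1$status == "ok" & p2$status == "ok"
  expect_true(any(ok))
  expect_equal(p1$fc[ok], p2$fc[ok], tolerance = 1e-9)
  # change signs are scale-free even where a rate saturates at the floor
  expect_equal(p1$pred_sign, p2$pred_sign)
})

test_that("similarity ratio counts agreements under both policies", {
  ref <- sign_table("ref", c(a = 1, b = -1, c = 1, d = -1))
  expect_equal(similarity_ratio(c(a = 1, b = -1, c = 1, d = -1), ref)$sr, 1)
  expect_equal(similarity_ratio(c(a = -1, b = 1, c = -1, d = 1), ref)$sr, 0)
  expect_equal(similarity_ratio(c(a = 1, b = -1, c = 1, d = 1), ref)$sr, 0.75)
  # missing predictions count as zero
  expect_equal(similarity_ratio(c(a = 1), ref)$sr, 0.25)
  # or are dropped from the denominator on request
  expect_warning(
    sr_drop <- similarity_ratio(c(a = 1), ref, missing = "drop"), "dropping")
  expect_equal(sr_drop$sr, 1)
  expect_equal(sr_drop$denominator, 1)
  # 0/0 agreement counts under policy 'all' but not 'defined_only'
  ref0 <- sign_table("ref0", c(a = 0, b = 1))
  expect_equal(similarity_ratio(c(a = 0, b = 1), ref0, policy = "all")$sr, 1)
  expect_equal(similarity_ratio(c(a = 0, b = 1), ref0,
                                policy = "defined_only")$denominator, 1)
  expect_error(sign_table("empty", stats::setNames(integer(0), character(0))))
})

test_that("similarity matches exhaustive enumeration for small sign vectors", {
  for (n in 2:5) {
    mets <- paste0("m", seq_len(n))
    grids <- expand.grid(rep(list(c(-1L, 0L, 1L)), n))
    # a fixed reference per n; predictions sweep the full 3^n cube
    refv <- stats::setNames(rep(c(1L, -1L, 0L), length.out = n), mets)
    ref <- sign_table("ref", refv)
    for (i in seq_len(nrow(grids))) {
      pred <- stats::setNames(unlist(grids[i, ]), mets)
      got <- similarity_ratio(pred, ref, policy = "all")
      want <- brute_similarity(pred, refv, policy = "all")
      expect_identical(got$n_agree, want$agree)
      expect_equal(got$sr, want$sr)
    }
  }
})

test_that("gene ranking is descending with deterministic ties", {
  reports <- list(list(gene = "g1", sr = list(exp = 0.5)),
                  list(gene = "g3", sr = list(exp = 0.9)),
                  list(gene = "g2", sr = list(exp = 0.7)))
  rk <- rank_genes(reports, "exp")
  expect_equal(rk$gene, c("g3", "g2", "g1"))
  ties <- list(list(gene = "b", sr = list(exp = 0.5)),
               list(gene = "a", sr = list(exp = 0.5)))
  expect_equal(rank_genes(ties, "exp")$gene, c("a", "b"))
  expect_error(rank_genes(reports, "missing"), "lacks reference")
})

test_that("packaged sign tables load and expose the documented discrepancy", {
  exp_tb <- read_sign_table(extdata("table1_signs_experiment.tsv"))
  expect_equal(exp_tb$n_total, 35)
  expect_identical(exp_tb$label, "experiment")
  war_tb <- read_sign_table(extdata("warburg_signs_synthetic.tsv"))
  expect_equal(war_tb$n_total, 21)
  # the printed per-gene arrow columns and the printed similarity row do not
  # reconcile exactly under either denominator policy; the matrix fixture
  # exists so the discrepancy stays measurable rather than hidden
  mat <- utils::read.delim(extdata("table1_sign_matrix.tsv"))
  printed <- utils::read.delim(extdata("table1_printed_similarity.tsv"))
  expect_equal(nrow(mat), 35)
  expect_equal(nrow(printed), 16)
  agree <- vapply(printed$gene, function(g)
    sum(mat[[g]] == mat$exp), integer(1))
  # printed ratios are consistent with a 36-entry denominator in granularity
  expect_true(all(abs(printed$sr_experiment * 36 -
                      round(printed$sr_experiment * 36)) < 0.02))
  # the transcription supports recomputation of per-gene agreement counts
  expect_true(all(agree >= 0 & agree <= 35))
})
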