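test_that("regulated flux value is the exact closed-form interpolation", {
  expect_equal(regulated_flux_value(2, 0, 5, 1, "up"), 5)
  expect_equal(regulated_flux_value(2, 0, 5, 0, "up"), 2)
  expect_equal(regulated_flux_value(2, 0, 5, 0.5, "down"), 1)
  # exactness over a grid of tuples
  for (basal in c(0, 0.5, 2, 4.9)) {
    for (delta in seq(0, 1, by = 0.125)) {
      expect_identical(regulated_flux_value(basal, 0, 5, delta, "up"),
                       basal + delta * (5 - basal))
      expect_identical(regulated_flux_value(basal, 0, 5, delta, "down"),
                       basal + delta * (0 - basal))
    }
  }
  expect_error(regulated_flux_value(2, 0, 5, 1.2, "up"), "delta")
  expect_error(regulated_flux_value(9, 0, 5, 0.5, "up"), "outside its range")
})

test_that("regulation strength is monotone in the regulated value", {
  deltas <- seq(0, 1, by = 0.1)
  ups <- vapply(deltas, function(d) regulated_flux_value(2, 0, 7, d, "up"),
                numeric(1))
  dns <- vapply(deltas, function(d) regulated_flux_value(2, 0, 7, d, "down"),
                numeric(1))
  expect_true(all(diff(ups) >= 0))
  expect_true(all(diff(dns) <= 0))
})

toy_cache <- function() {
  m <- make_toy_liver_model()
  cache <- run_normal_state(m, genes = model_genes(m))
  cache
}

test_that("build_regulation resolves the four modes on the toy model", {
  cache <- toy_cache()
  m <- cache$model; sys <- cache$system

  # up at full strength on an irreversible single-gene reaction
  sp <- build_regulation(m, sys, "Pdha1", "up", 1, cache$normal, cache$ranges)
  expect_equal(nrow(sp$targets), 1)
  k <- match("TCA_f", cache$ranges$col_id)
  expect_equal(sp$targets$value, cache$ranges$v_max[k])

  # knockout of a gene mapping one reaction with a reversible partner
  spk <- build_regulation(m, sys, "Ldha", "knockout")
  expect_equal(sort(spk$targets$col_id), c("LDH_b", "LDH_f"))
  expect_true(all(spk$targets$value == 0))

  # knockout of the three-reaction decarboxylase gene fixes three zeros
  spd <- build_regulation(m, sys, "Ddc", "knockout")
  expect_equal(nrow(spd$targets), 3)

  # coupled up-regulation of a reversible reaction pins both directions high
  spc <- build_regulation(m, sys, "Ldha", "coupled_up", 1,
                          cache$normal, cache$ranges)
  expect_setequal(spc$targets$col_id, c("LDH_f", "LDH_b"))
  for (j in seq_len(nrow(spc$targets))) {
    kk <- match(spc$targets$col_id[j], cache$ranges$col_id)
    expect_equal(spc$targets$value[j], cache$ranges$v_max[kk])
  }

  # unknown gene errors
  expect_error(build_regulation(m, sys, "Nope", "up", 1,
                                cache$normal, cache$ranges), "not in model")
})

test_that("up-regulating a reversible reaction follows the basal net direction", {
  cache <- toy_cache()
  # LDH basal net flux is forward (pyruvate -> lactate), so up regulates _f
  sp <- build_regulation(cache$model, cache$system, "Ldha", "up", 1,
                         cache$normal, cache$ranges)
  expect_true("LDH_f" %in% sp$targets$col_id)
  held <- sp$targets[sp$targets$col_id == "LDH_b", ]
  expect_equal(held$value, unname(cache$normal$v["LDH_b"]))
})

test_that("apply_regulation merges disjoint specs and rejects conflicts", {
  cache <- toy_cache()
  m <- cache$model; sys <- cache$system
  spA <- build_regulation(m, sys, "Pdha1", "knockout")
  spB <- build_regulation(m, sys, "Gls2", "knockout")
  merged <- apply_regulation(sys, list(spA, spB))
  expect_equal(sort(names(merged)), sort(c("TCA_f", "GLS_f")))
  # idempotent: applying the same spec twice is the same map
  expect_equal(apply_regulation(sys, list(spA, spA)), apply_regulation(sys, spA))
  # conflict: same column, different values
  spU <- build_regulation(m, sys, "Pdha1", "up", 1, cache$normal, cache$ranges)
  expect_error(apply_regulation(sys, list(spA, spU)), "conflict")
  # empty spec list -> empty map
  expect_length(apply_regulation(sys, list()), 0)
})

test_that("delta = 0 leaves the deficient state equal to the normal state", {
  cache <- toy_cache()
  for (g in c("Ddc", "Gls2", "Pfkl")) {
    sp <- build_regulation(cache$model, cache$system, g, "up", 0,
                           cache$normal, cache$ranges)
    ts <- solve_two_stage(cache$system, apply_regulation(cache$system, sp))
    expect_identical(ts$state$status, "optimal")
    expect_lt(max(abs(ts$state$v - cache$normal$v)), 1e-6)
    expect_equal(ts$z_star, cache$z_star, tolerance = 1e-8)
  }
})

test_that("knockouts can only lower the optimum", {
  cache <- toy_cache()
  for (g in c("Pdha1", "Gls2", "Pfkl", "Maoa")) {
    sp <- build_regulation(cache$model, cache$system, g, "knockout")
    st <- maximize_objective(cache$system, apply_regulation(cache$system, sp))
    expect_identical(st$status, "optimal")
    expect_lte(st$z, cache$z_star + 1e-9)
  }
})

test_that("unconstrained up-regulation reaches full strength", {
  cache <- toy_cache()
  mf <- max_feasible_delta(cache$model, cache$system, "Gls2", "up",
                           cache$normal, cache$ranges)
  expect_equal(mf$delta_star, 1)
})

test_that("the capped-branch construction caps the strength where designed", {
  m <- make_capped_branch_model(delta_star = 0.40)
  cache <- run_normal_state(m, genes = "Cap")
  mf <- max_feasible_delta(m, cache$system, "Cap", "up",
                           cache$normal, cache$ranges, tol = 0.005)
  expect_lt(abs(mf$delta_star - 0.40), 0.005 + 1e-9)
  # every reported strength is itself feasible
  sp <- build_regulation(m, cache$system, "Cap", "up", mf$delta_star,
                         cache$normal, cache$ranges)
  st <- maximize_objective(cache$system, apply_regulation(cache$system, sp))
  expect_identical(st$status, "optimal")
  # and nudging past the cap is not
  sp2 <- build_regulation(m, cache$system, "Cap", "up",
                          min(1, mf$delta_star + 0.01),
                          cache$normal, cache$ranges)
  st2 <- maximize_objective(cache$system, apply_regulation(cache$system, sp2))
  expect_identical(st2$status, "infeasible")
})

test_that("feasible strengths nest below the cap on the capped toy", {
  m <- make_capped_branch_model(delta_star = 0.40)
  cache <- run_normal_state(m, genes = "Cap")
  for (d in c(0, 0.1, 0.25, 0.39)) {
    sp <- build_regulation(m, cache$system, "Cap", "up", d,
                           cache$normal, cache$ranges)
    st <- maximize_objective(cache$system, apply_regulation(cache$system, sp))
    expect_identical(st$status, "optimal")
  }
  for (d in c(0.45, 0.7, 1)) {
    sp <- build_regulation(m, cache$system, "Cap", "up", d,
                           cache$normal, cache$ranges)
    st <- maximize_objective(cache$system, apply_regulation(cache$system, sp))
    expect_identical(st$status, "infeasible")
  }
})
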