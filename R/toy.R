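# Seeded generators for desk-scale, mass-balanced toy networks with known
# ground truth: a three-compartment hepatocyte caricature, a capped-branch
# model with an exactly known maximal regulation strength, and random sparse
# systems small enough for exhaustive/oracle checking.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Toy model generation parameters
#'
#' @param seed integer seed (the default topology is deterministic; the seed
#'   feeds derived randomised utilities)
#' @param include_tca include the mitochondrial pyruvate / TCA branch
#' @param include_glutaminolysis include glutamine uptake ->
#'   glutamate -> alpha-ketoglutarate anaplerosis
#' @param n_parallel_routes number of decarboxylase precursor branches
#'   carrying the `Ddc` label (default 3)
#' @param capacity_scale positive multiplier on all uptake capacities
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(seed = 1L, include_tca = TRUE,
                     include_glutaminolysis = TRUE,
                     n_parallel_routes = 3L, capacity_scale = 1) {
  stopifnot(n_parallel_routes >= 1L, capacity_scale > 0)
  structure(list(seed = as.integer(seed), include_tca = include_tca,
                 include_glutaminolysis = include_glutaminolysis,
                 n_parallel_routes = as.integer(n_parallel_routes),
                 capacity_scale = capacity_scale), class = "toy_spec")
}

#' Toy hepatocyte model
#'
#' A three-compartment (extracellular / cytosol / mitochondrion),
#' mass-balanced caricature of central liver carbon metabolism: glucose
#' uptake and lumped glycolysis, lactate production and secretion,
#' oxygen-limited mitochondrial pyruvate oxidation, glutaminolysis
#' (glutamine -> glutamate -> alpha-ketoglutarate) feeding an oxidative
#' ATP branch, and an aromatic-amino-acid decarboxylase side branch (gene
#' `Ddc`, one reaction per parallel precursor route) whose amine product
#' must be oxidatively deaminated in the mitochondrion using
#' alpha-ketoglutarate as amino acceptor. The ATP demand in the cytosol is
#' the objective. Capacities are chosen so that cytosolic pyruvate routing
#' (lactate vs mitochondrion) and mitochondrial oxygen are genuinely
#' contested: up-regulating `Ddc` diverts oxygen and demands
#' alpha-ketoglutarate, reproducing the aerobic-glycolysis shift (lactate
#' and glutamine up, mitochondrial pyruvate transport down) as a property
#' of the topology.
#'
#' Default capacities (times `capacity_scale`): glucose uptake 10, oxygen
#' 10, glutamine 20, each decarboxylase precursor 1; internal caps 1000.
#'
#' @param spec a `toy_spec`
#' @return a `metabolic_model` with objective metabolite `atp_c`
#' @export
make_toy_liver_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  s <- spec$capacity_scale
  big <- 1000 * s
  pre <- c("dopa", "htp", "trp",
           if (spec$n_parallel_routes > 3L)
             paste0("aa", seq_len(spec$n_parallel_routes - 3L) + 3L))
  pre <- pre[seq_len(spec$n_parallel_routes)]

  mets <- list(
    c("glc_e", "glucose", "e"), c("glc_c", "glucose", "c"),
    c("pyr_c", "pyruvate", "c"), c("lac_c", "lactate", "c"),
    c("lac_e", "lactate", "e"), c("atp_c", "ATP", "c"),
    c("o2_e", "oxygen", "e"),
    c("amn_c", "biogenic amine", "c"), c("amn_m", "biogenic amine", "m"),
    c("waste_m", "deaminated waste", "m"), c("waste_e", "deaminated waste", "e"))
  if (spec$include_tca)
    mets <- c(mets, list(c("pyr_m", "pyruvate", "m"), c("atp_m", "ATP", "m"),
                         c("o2_m", "oxygen", "m")))
  else
    mets <- c(mets, list(c("atp_m", "ATP", "m"), c("o2_m", "oxygen", "m")))
  if (spec$include_glutaminolysis)
    mets <- c(mets, list(c("gln_e", "glutamine", "e"), c("gln_m", "glutamine", "m"),
                         c("glu_m", "glutamate", "m"),
                         c("akg_m", "alpha-ketoglutarate", "m")))
  for (p in pre)
    mets <- c(mets, list(c(paste0(p, "_e"), p, "e"), c(paste0(p, "_c"), p, "c")))
  md <- data.frame(id = vapply(mets, `[`, "", 1),
                   name = vapply(mets, `[`, "", 2),
                   compartment = vapply(mets, `[`, "", 3),
                   stringsAsFactors = FALSE)

  rx <- list(
    list(id = "EX_glc", stoich = c(glc_e = -1), lb = -10 * s, ub = big,
         reversible = TRUE),
    list(id = "GLCt", stoich = c(glc_e = -1, glc_c = 1), lb = 0, ub = big,
         genes = "Slc2a2"),
    list(id = "GLYC", stoich = c(glc_c = -1, pyr_c = 2, atp_c = 2),
         lb = 0, ub = big, genes = "Pfkl"),
    list(id = "LDH", stoich = c(pyr_c = -1, lac_c = 1), lb = -big, ub = big,
         reversible = TRUE, genes = "Ldha"),
    list(id = "LACt", stoich = c(lac_c = -1, lac_e = 1), lb = 0, ub = big),
    list(id = "EX_lac", stoich = c(lac_e = -1), lb = 0, ub = big),
    list(id = "EX_o2", stoich = c(o2_e = -1), lb = -10 * s, ub = 0,
         reversible = TRUE),
    list(id = "O2t", stoich = c(o2_e = -1, o2_m = 1), lb = 0, ub = big),
    list(id = "ATPtm", stoich = c(atp_m = -1, atp_c = 1), lb = 0, ub = big),
    list(id = "AMNtm", stoich = c(amn_c = -1, amn_m = 1), lb = 0, ub = big),
    list(id = "WASTEt", stoich = c(waste_m = -1, waste_e = 1), lb = 0, ub = big),
    list(id = "EX_waste", stoich = c(waste_e = -1), lb = 0, ub = big))
  if (spec$include_tca)
    rx <- c(rx, list(
      list(id = "PYRtm", stoich = c(pyr_c = -1, pyr_m = 1), lb = 0, ub = big,
           genes = "Mpc1"),
      list(id = "TCA", stoich = c(pyr_m = -1, o2_m = -1, atp_m = 5),
           lb = 0, ub = big, genes = "Pdha1")))
  if (spec$include_glutaminolysis)
    rx <- c(rx, list(
      list(id = "EX_gln", stoich = c(gln_e = -1), lb = -20 * s, ub = 0,
           reversible = TRUE),
      list(id = "GLNt", stoich = c(gln_e = -1, gln_m = 1), lb = 0, ub = big,
           genes = "Slc1a5"),
      list(id = "GLS", stoich = c(gln_m = -1, glu_m = 1), lb = 0, ub = big,
           genes = "Gls2"),
      list(id = "GDH", stoich = c(glu_m = -1, akg_m = 1), lb = 0, ub = big,
           genes = "Glud1"),
      list(id = "AKGDH", stoich = c(akg_m = -1, o2_m = -1, atp_m = 4),
           lb = 0, ub = big, genes = "Ogdh")))
  # amine oxidation needs the amino acceptor only when glutaminolysis exists;
  # without it the branch ends in a plain oxidase so the model stays feasible
  aox_st <- if (spec$include_glutaminolysis)
    c(amn_m = -1, akg_m = -1, o2_m = -1, waste_m = 1)
  else c(amn_m = -1, o2_m = -1, waste_m = 1)
  rx <- c(rx, list(list(id = "AOX", stoich = aox_st, lb = 0, ub = big,
                        genes = "Maoa")))
  for (p in pre) {
    pe <- paste0(p, "_e"); pc <- paste0(p, "_c")
    rx <- c(rx, list(
      list(id = paste0("EX_", p), stoich = stats::setNames(-1, pe),
           lb = -1 * s, ub = 0, reversible = TRUE),
      list(id = paste0(toupper(p), "t"),
           stoich = stats::setNames(c(-1, 1), c(pe, pc)), lb = 0, ub = big),
      list(id = paste0("DDC_", p),
           stoich = stats::setNames(c(-1, 1), c(pc, "amn_c")),
           lb = 0, ub = big, genes = "Ddc")))
  }
  metabolic_model(md, rx, objective = list(metabolite = "atp_c"),
                  boundary_compartment = "e")
}

#' Capped-branch model with known maximal regulation strength
#'
#' A precursor with uptake capacity `supply` feeds `n_branches` parallel
#' product branches, all labelled with one gene; each branch is forced to a
#' basal flux `basal` by a minimal-secretion bound, and the last branch has
#' its own capacity cap. Up-regulating the gene fixes every branch at
#' `basal + delta * (v_max - basal)` simultaneously, and the shared supply
#' makes that jointly feasible exactly up to a known strength: the cap on
#' the last branch is back-computed so that the largest feasible delta
#' equals `delta_star`.
#'
#' The construction requires `delta_star` in
#' `[(supply - n*basal) / (n * (supply - (n-1)*basal - basal)), 0.5)`
#' for `n = n_branches`; the default (0.40 with three branches, supply 10,
#' basal 1) sits inside it.
#'
#' @param delta_star the intended largest feasible regulation strength
#' @param supply shared precursor uptake capacity
#' @param basal forced basal flux per branch
#' @param n_branches number of parallel branches (>= 2)
#' @return a `metabolic_model`; the regulated gene is `"Cap"`
#' @export
make_capped_branch_model <- function(delta_star = 0.40, supply = 10,
                                     basal = 1, n_branches = 3L) {
  stopifnot(n_branches >= 2L, supply > n_branches * basal)
  vmax_open <- supply - (n_branches - 1) * basal
  spare <- supply - n_branches * basal
  cap_last <- basal + spare / delta_star -
    (n_branches - 1) * (vmax_open - basal)
  if (cap_last <= basal || cap_last > vmax_open + 1e-9)
    stop("delta_star = ", delta_star, " not representable with these ",
         "supply/basal settings")
  mets <- list(c("pre_e", "precursor", "e"), c("pre_c", "precursor", "c"),
               c("atp_c", "ATP", "c"))
  rx <- list(
    list(id = "EX_pre", stoich = c(pre_e = -1), lb = -supply, ub = 0,
         reversible = TRUE),
    list(id = "PREt", stoich = c(pre_e = -1, pre_c = 1), lb = 0, ub = 1000),
    list(id = "PYK", stoich = c(pre_c = -1, atp_c = 1), lb = 0, ub = 1000))
  for (k in seq_len(n_branches)) {
    xm <- sprintf("x%d", k)
    mets <- c(mets, list(c(paste0(xm, "_c"), xm, "c"),
                         c(paste0(xm, "_e"), xm, "e")))
    ubk <- if (k == n_branches) cap_last else 1000
    rx <- c(rx, list(
      list(id = sprintf("BR%d", k),
           stoich = stats::setNames(c(-1, 1), c("pre_c", paste0(xm, "_c"))),
           lb = 0, ub = ubk, genes = "Cap"),
      list(id = sprintf("X%dt", k),
           stoich = stats::setNames(c(-1, 1), paste0(xm, c("_c", "_e"))),
           lb = 0, ub = 1000),
      list(id = sprintf("EX_x%d", k),
           stoich = stats::setNames(-1, paste0(xm, "_e")),
           lb = basal, ub = 1000)))
  }
  md <- data.frame(id = vapply(mets, `[`, "", 1),
                   name = vapply(mets, `[`, "", 2),
                   compartment = vapply(mets, `[`, "", 3),
                   stringsAsFactors = FALSE)
  metabolic_model(md, rx, objective = list(metabolite = "atp_c"),
                  boundary_compartment = "e")
}

#' Reference sign table with a controlled number of agreements
#'
#' Builds a table agreeing with `pred_signs` on exactly `n_agree` entries:
#' agreement entries copy the prediction; disagreement entries flip non-zero
#' signs and replace zeros with a random non-zero sign. Downstream,
#' [similarity_ratio()] under policy `"all"` returns exactly
#' `n_agree / length(pred_signs)`.
#'
#' @param pred_signs named vector of predicted signs
#' @param n_agree number of agreeing entries, `0 <= n_agree <= length(pred_signs)`
#' @param seed seed choosing which entries agree
#' @param label table label (default `"constructed"`)
#' @return a `sign_table`
#' @export
make_sign_table <- function(pred_signs, n_agree, seed = 1L,
                            label = "constructed") {
  n <- length(pred_signs)
  if (n_agree < 0 || n_agree > n)
    stop("n_agree must lie in [0, ", n, "], got ", n_agree)
  with_seed(seed, {
    agree <- sample(n, n_agree)
    ref <- as.integer(pred_signs)
    for (k in setdiff(seq_len(n), agree)) {
      ref[k] <- if (ref[k] != 0L) -ref[k] else sample(c(-1L, 1L), 1)
    }
    sign_table(label, stats::setNames(ref, names(pred_signs)))
  })
}

#' Random mass-balanced toy system
#'
#' A seeded sparse random network at oracle-enumerable scale: a guaranteed
#' substrate-to-objective backbone (uptake, transport, conversion chain,
#' demand) plus random internal conversions, each consuming and producing
#' at least one metabolite so no reaction is a pure source or sink. All
#' bounds are finite; a positive objective flux is feasible by
#' construction. Deterministic for a fixed seed.
#'
#' @param n_mets number of cytosolic metabolites (2..12)
#' @param n_rxns total number of reactions (must allow the backbone;
#'   at most 14)
#' @param seed integer seed
#' @return a `metabolic_model`
#' @export
make_random_balanced_system <- function(n_mets = 8L, n_rxns = 12L, seed = 1L) {
  stopifnot(n_mets >= 2L, n_mets <= 12L, n_rxns <= 14L)
  with_seed(seed, {
    chain_len <- min(n_mets, max(2L, n_rxns - 3L))
    chain <- sample(n_mets, chain_len)
    mids <- paste0("m", seq_len(n_mets), "_c")
    md <- rbind(
      data.frame(id = "s_e", name = "substrate", compartment = "e",
                 stringsAsFactors = FALSE),
      data.frame(id = mids, name = paste0("m", seq_len(n_mets)),
                 compartment = "c", stringsAsFactors = FALSE))
    rx <- list(
      list(id = "EX_s", stoich = c(s_e = -1), lb = -round(runif(1, 5, 15), 2),
           ub = 0, reversible = TRUE),
      list(id = "Ts", stoich = stats::setNames(c(-1, 1), c("s_e", mids[chain[1]])),
           lb = 0, ub = 100))
    for (k in seq_len(chain_len - 1L)) {
      rx <- c(rx, list(list(
        id = paste0("C", k),
        stoich = stats::setNames(c(-1, 1), mids[chain[c(k, k + 1L)]]),
        lb = 0, ub = round(runif(1, 8, 100), 2))))
    }
    obj_met <- mids[chain[chain_len]]
    rx <- c(rx, list(list(id = "DM_obj",
                          stoich = stats::setNames(-1, obj_met),
                          lb = 0, ub = 100, exchange = TRUE)))
    extra <- n_rxns - length(rx)
    k <- 0L
    while (k < extra) {
      k <- k + 1L
      # mass-conserving conversion: total consumed equals total produced,
      # so no internal reaction can act as a source
      ns <- sample(2:3, 1)
      who <- sample(n_mets, ns)
      coef <- if (ns == 2L) {
        amt <- sample(1:2, 1); c(-amt, amt)
      } else {
        if (runif(1) < 0.5) c(-2, 1, 1) else c(-1, -1, 2)
      }
      rev <- runif(1) < 0.3
      ubk <- round(runif(1, 2, 30), 2)
      rx <- c(rx, list(list(id = paste0("R", k),
                            stoich = stats::setNames(coef, mids[who]),
                            lb = if (rev) -ubk else 0, ub = ubk,
                            reversible = rev)))
    }
    metabolic_model(md, rx, objective = list(reaction = "DM_obj"),
                    boundary_compartment = "e")
  })
}
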