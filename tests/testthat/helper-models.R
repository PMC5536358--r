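# Small hand-built models reused across tests.

mets_ec <- function(...) {
  ids <- c(...)
  data.frame(id = ids, name = ids,
             compartment = ifelse(grepl("_e$", ids), "e", "c"),
             stringsAsFactors = FALSE)
}

# glc_e -(uptake <= 10)-> glc_c -> atp_c -> demand; optimum 10
chain_model <- function(uptake = 10) {
  metabolic_model(
    mets_ec("glc_e", "glc_c", "atp_c"),
    list(
      list(id = "EX_glc", stoich = c(glc_e = -1), lb = -uptake, ub = 0,
           reversible = TRUE),
      list(id = "T", stoich = c(glc_e = -1, glc_c = 1), lb = 0, ub = 100),
      list(id = "CONV", stoich = c(glc_c = -1, atp_c = 1), lb = 0, ub = 100,
           genes = "GeneA")),
    objective = list(metabolite = "atp_c"))
}

# two routes of capacities 4 and 7 into the objective; optimum 11
two_route_model <- function() {
  metabolic_model(
    mets_ec("s_e", "s_c", "atp_c"),
    list(
      list(id = "EX_s", stoich = c(s_e = -1), lb = -100, ub = 0,
           reversible = TRUE),
      list(id = "T", stoich = c(s_e = -1, s_c = 1), lb = 0, ub = 100),
      list(id = "R1", stoich = c(s_c = -1, atp_c = 1), lb = 0, ub = 4),
      list(id = "R2", stoich = c(s_c = -1, atp_c = 1), lb = 0, ub = 7)),
    objective = list(metabolite = "atp_c"))
}

# two identical routes; the norm-minimal solution splits the flux equally
parallel_model <- function(cap = 10) {
  metabolic_model(
    mets_ec("s_e", "s_c", "atp_c"),
    list(
      list(id = "EX_s", stoich = c(s_e = -1), lb = -cap, ub = 0,
           reversible = TRUE),
      list(id = "T", stoich = c(s_e = -1, s_c = 1), lb = 0, ub = 100),
      list(id = "RA", stoich = c(s_c = -1, atp_c = 1), lb = 0, ub = cap),
      list(id = "RB", stoich = c(s_c = -1, atp_c = 1), lb = 0, ub = cap)),
    objective = list(metabolite = "atp_c"))
}

# chain plus a detached futile two-cycle fa <-> fb
futile_cycle_model <- function() {
  metabolic_model(
    mets_ec("glc_e", "glc_c", "atp_c", "fa_c", "fb_c"),
    list(
      list(id = "EX_glc", stoich = c(glc_e = -1), lb = -10, ub = 0,
           reversible = TRUE),
      list(id = "T", stoich = c(glc_e = -1, glc_c = 1), lb = 0, ub = 100),
      list(id = "CONV", stoich = c(glc_c = -1, atp_c = 1), lb = 0, ub = 100),
      list(id = "F1", stoich = c(fa_c = -1, fb_c = 1), lb = 0, ub = 10),
      list(id = "F2", stoich = c(fb_c = -1, fa_c = 1), lb = 0, ub = 10)),
    objective = list(metabolite = "atp_c"))
}

# chain plus a column with no route to the boundary (blocked)
blocked_column_model <- function() {
  metabolic_model(
    mets_ec("glc_e", "glc_c", "atp_c", "x_c", "y_c"),
    list(
      list(id = "EX_glc", stoich = c(glc_e = -1), lb = -10, ub = 0,
           reversible = TRUE),
      list(id = "T", stoich = c(glc_e = -1, glc_c = 1), lb = 0, ub = 100),
      list(id = "CONV", stoich = c(glc_c = -1, atp_c = 1), lb = 0, ub = 100),
      list(id = "BLK", stoich = c(x_c = -1, y_c = 1), lb = 0, ub = 50)),
    objective = list(metabolite = "atp_c"))
}

# net ATP created by an uncapped internal cycle: stage-1 LP is unbounded
unbounded_model <- function() {
  metabolic_model(
    mets_ec("a_c", "b_c", "atp_c"),
    list(
      list(id = "R1", stoich = c(a_c = -1, b_c = 1, atp_c = 1), lb = 0, ub = Inf),
      list(id = "R2", stoich = c(b_c = -1, a_c = 1), lb = 0, ub = Inf)),
    objective = list(metabolite = "atp_c"))
}

extdata <- function(...) {
  p <- system.file("extdata", ..., package = "hepaflux")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", ...)
  p
}
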