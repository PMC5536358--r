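# Gene-level regulation constraints: interpolated flux fixing between the
# basal flux and its normal-state extreme, knockouts, and coupled
# forward/backward up-regulation, plus the maximal-feasible-strength search.

#' Regulated flux value
#'
#' Linear interpolation between the basal flux and the normal-state extreme:
#' up-regulation returns `basal + delta * (v_max - basal)`, down-regulation
#' `basal + delta * (v_min - basal)`. `delta = 0` reproduces the basal flux;
#' `delta = 1` pins the flux to the extreme.
#'
#' @param basal basal (normal-state, norm-minimal) flux of the column
#' @param v_min,v_max the column's flux range at the normal state
#' @param delta regulation strength in `[0, 1]`
#' @param mode `"up"` or `"down"`
#' @return the fixed flux value, guaranteed inside `[v_min, v_max]`
#' @export
regulated_flux_value <- function(basal, v_min, v_max, delta,
                                 mode = c("up", "down")) {
  mode <- match.arg(mode)
  if (!is.finite(delta) || delta < 0 || delta > 1)
    stop("delta must lie in [0, 1], got ", delta)
  tol <- 1e-6 * max(1, abs(v_min), abs(v_max))
  if (basal < v_min - tol || basal > v_max + tol)
    stop("basal flux ", basal, " outside its range [", v_min, ", ", v_max, "]")
  basal <- min(max(basal, v_min), v_max)
  val <- if (mode == "up") basal + delta * (v_max - basal)
         else basal + delta * (v_min - basal)
  min(max(val, v_min), v_max)
}

#' Build a regulation specification for one gene
#'
#' Resolves a gene's dysregulation mode into fixed flux values on the
#' columns of its mapped reactions:
#' \describe{
#'   \item{up / down}{the regulated direction of each reaction receives the
#'     interpolated value; the opposite direction is fixed at its basal
#'     flux. For a reversible reaction the regulated direction follows the
#'     sign of the basal net flux (forward when non-negative).}
#'   \item{knockout}{both directions fixed to zero.}
#'   \item{coupled_up}{both directions up-regulated simultaneously, each
#'     against its own range (equilibrium-preserving overexpression of a
#'     forward/backward pair).}
#' }
#'
#' @param model a `metabolic_model`
#' @param system the matching `irreversible_system`
#' @param gene gene identifier (must map to at least one reaction)
#' @param mode one of `"up"`, `"down"`, `"knockout"`, `"coupled_up"`
#' @param delta regulation strength in `[0, 1]` (ignored for knockout)
#' @param normal the normal-state (stage-2) `flux_state`
#' @param ranges `flux_range()` output covering the gene's columns
#' @param reactions optional explicit reaction ids overriding the
#'   gene-to-reaction map (to reproduce externally curated target tables)
#' @return object of class `regulation_spec` with a `targets` data.frame
#'   (`col_id`, `value`)
#' @export
build_regulation <- function(model, system, gene,
                             mode = c("up", "down", "knockout", "coupled_up"),
                             delta = 1, normal = NULL, ranges = NULL,
                             reactions = NULL) {
  mode <- match.arg(mode)
  rids <- reactions %||% gene_to_reactions(model, gene)
  if (length(rids) == 0L) stop("gene not in model: ", gene)
  missing_r <- setdiff(rids, model$reactions$id)
  if (length(missing_r))
    stop("regulated reaction(s) not in model: ", paste(missing_r, collapse = ", "))

  targets <- data.frame(col_id = character(0), value = numeric(0),
                        stringsAsFactors = FALSE)
  add <- function(col, val) targets <<- rbind(
    targets, data.frame(col_id = col, value = val, stringsAsFactors = FALSE))

  need_state <- mode != "knockout"
  if (need_state && (is.null(normal) || is.null(ranges)))
    stop("mode '", mode, "' needs the normal state and flux ranges")

  range_of <- function(col) {
    k <- match(col, ranges$col_id)
    if (is.na(k)) stop("ranges do not cover column ", col)
    ranges[k, ]
  }
  for (rid in rids) {
    cols <- reaction_columns(system, rid)
    fcol <- names(cols)[1]
    bcol <- if (length(cols) > 1L) names(cols)[2] else NULL
    if (mode == "knockout") {
      add(fcol, 0); if (!is.null(bcol)) add(bcol, 0)
    } else if (mode == "coupled_up") {
      rf <- range_of(fcol)
      add(fcol, regulated_flux_value(rf$v_basal, rf$v_min, rf$v_max, delta, "up"))
      if (!is.null(bcol)) {
        rb <- range_of(bcol)
        add(bcol, regulated_flux_value(rb$v_basal, rb$v_min, rb$v_max, delta, "up"))
      }
    } else {
      reg_col <- fcol; hold_col <- bcol
      if (!is.null(bcol)) {
        net <- unname(normal$v[fcol] - normal$v[bcol])
        if (net < 0) { reg_col <- bcol; hold_col <- fcol }
      }
      rr <- range_of(reg_col)
      add(reg_col, regulated_flux_value(rr$v_basal, rr$v_min, rr$v_max, delta, mode))
      if (!is.null(hold_col)) add(hold_col, unname(normal$v[hold_col]))
    }
  }
  structure(list(gene = gene, mode = mode, delta = delta,
                 targets = targets, reactions = rids,
                 source_ranges = if (need_state) ranges else NULL),
            class = "regulation_spec")
}

#' @export
print.regulation_spec <- function(x, ...) {
  cat("regulation_spec: gene ", x$gene, ", mode ", x$mode,
      if (x$mode != "knockout") paste0(", delta ", x$delta), "\n", sep = "")
  print(x$targets); invisible(x)
}

#' Resolve regulation specs into a fixed-constraint map
#'
#' Merges one or more `regulation_spec`s into the named fixed-value vector
#' consumed by [maximize_objective()] / [minimize_norm()]. Fixing the same
#' column to two different values is a conflict and errors; repeated
#' identical fixes are idempotent.
#'
#' @param system an `irreversible_system`
#' @param specs a `regulation_spec` or list of them
#' @return named numeric vector, column id -> fixed value
#' @export
apply_regulation <- function(system, specs) {
  if (inherits(specs, "regulation_spec")) specs <- list(specs)
  fixed <- numeric(0)
  for (sp in specs) {
    stopifnot(inherits(sp, "regulation_spec"))
    for (k in seq_len(nrow(sp$targets))) {
      col <- sp$targets$col_id[k]; val <- sp$targets$value[k]
      if (!col %in% system$cols$col_id)
        stop("regulation targets unknown column: ", col)
      if (col %in% names(fixed) && abs(fixed[col] - val) > 1e-9)
        stop("conflicting regulation on column ", col, ": ",
             fixed[col], " vs ", val)
      fixed[col] <- val
    }
  }
  fixed
}

#' Largest feasible regulation strength
#'
#' Bisection on `delta` in `[0, 1]`: returns the largest strength (within
#' `tol`) whose regulated stage-1 problem is feasible. `delta = 0` must be
#' feasible (it reproduces the normal state); `delta = 1` feasible
#' short-circuits the search.
#'
#' @inheritParams build_regulation
#' @param tol bisection tolerance on delta (default 0.005, i.e. strengths
#'   reportable to the nearest percent)
#' @return list with `delta_star`, the `regulation_spec` at `delta_star`,
#'   and `outcome` (list of `feasible`, `deficient_state`, `z`)
#' @export
max_feasible_delta <- function(model, system, gene,
                               mode = c("up", "down", "coupled_up"),
                               normal, ranges, tol = 0.005,
                               reactions = NULL) {
  mode <- match.arg(mode)
  feas <- function(delta) {
    sp <- build_regulation(model, system, gene, mode, delta, normal, ranges,
                           reactions = reactions)
    st <- maximize_objective(system, apply_regulation(system, sp))
    list(ok = identical(st$status, "optimal"), spec = sp, state = st)
  }
  f0 <- feas(0)
  if (!f0$ok)
    stop("regulated system infeasible at delta = 0; normal state corrupt")
  f1 <- feas(1)
  if (f1$ok)
    return(list(delta_star = 1, spec = f1$spec,
                outcome = list(feasible = TRUE, stage1 = f1$state, z = f1$state$z)))
  lo <- 0; hi <- 1; flo <- f0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- feas(mid)
    if (fm$ok) { lo <- mid; flo <- fm } else hi <- mid
  }
  list(delta_star = lo, spec = flo$spec,
       outcome = list(feasible = TRUE, stage1 = flo$state, z = flo$state$z))
}
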