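# Two-stage flux balance analysis: objective maximisation over the split
# system, then minimum-Euclidean-norm selection among the alternative optima.

BALANCE_TOL <- 1e-6       # reporting tolerance on mass balance
FEAS_TOL <- 1e-9          # solver feasibility tolerance
ZERO_FLUX_TOL <- 1e-9     # |v| below this is treated as zero

# assemble (A, b, lb, ub) with fixed columns folded in as lb = ub
assemble_bounds <- function(system, fixed = NULL) {
  lb <- system$cols$lb; ub <- system$cols$ub
  if (length(fixed)) {
    idx <- match(names(fixed), system$cols$col_id)
    if (anyNA(idx))
      stop("fixed map names unknown column(s): ",
           paste(names(fixed)[is.na(idx)], collapse = ", "))
    bad <- fixed < lb[idx] - 1e-7 | fixed > ub[idx] + 1e-7
    if (any(bad))
      stop("fixed value(s) outside column bounds: ",
           paste(names(fixed)[bad], collapse = ", "))
    lb[idx] <- ub[idx] <- unname(fixed)
  }
  list(lb = lb, ub = ub)
}

new_flux_state <- function(system, x, status, unbounded_col = NA_character_) {
  if (is.null(x)) {
    return(structure(list(v = NULL, z = NA_real_, sq_norm = NA_real_,
                          status = status, unbounded_col = unbounded_col),
                     class = "flux_state"))
  }
  x[abs(x) < ZERO_FLUX_TOL] <- 0
  v <- stats::setNames(x, system$cols$col_id)
  structure(list(v = v,
                 z = sum(system$obj * x),
                 sq_norm = sum(x[system$cols$internal]^2),
                 status = status, unbounded_col = unbounded_col),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state [", x$status, "]", sep = "")
  if (identical(x$status, "optimal"))
    cat(": z = ", format(x$z), ", internal sq_norm = ",
        format(x$sq_norm), sep = "")
  if (identical(x$status, "unbounded") && !is.na(x$unbounded_col))
    cat(" (unbounded column: ", x$unbounded_col, ")", sep = "")
  cat("\n"); invisible(x)
}

#' Maximise the objective flux (stage 1)
#'
#' Solves the steady-state linear program: maximise the objective flux
#' subject to mass balance `N (v_f - v_b) = 0`, column bounds, and any fixed
#' regulation values. Infeasible fixed constraints yield a `flux_state` with
#' status `"infeasible"`, not an error; an unbounded objective is reported
#' with the offending column named.
#'
#' @param system an `irreversible_system`
#' @param fixed named numeric vector, column id -> fixed flux value
#' @return a `flux_state` (`v`, `z`, `sq_norm`, `status`)
#' @export
maximize_objective <- function(system, fixed = NULL) {
  bb <- assemble_bounds(system, fixed)
  A <- as.matrix(system$S)
  r <- simplex_lp(system$obj, A, rep(0, nrow(A)), bb$lb, bb$ub, maximize = TRUE)
  if (identical(r$status, "unbounded")) {
    col <- if (!is.na(r$unbounded_var)) system$cols$col_id[r$unbounded_var] else NA_character_
    return(new_flux_state(system, NULL, "unbounded", col))
  }
  if (!identical(r$status, "optimal"))
    return(new_flux_state(system, NULL, r$status))
  new_flux_state(system, r$x, "optimal")
}

#' Minimum-norm flux selection (stage 2)
#'
#' Among all flux distributions achieving at least the stage-1 objective
#' `z_star`, returns the one minimising the squared sum of internal fluxes
#' (forward and backward columns of non-exchange reactions). Strict convexity
#' on the internal columns makes that part of the solution unique; the
#' non-internal columns carry a negligible weight so the reported vector is
#' fully determined.
#'
#' @param system an `irreversible_system`
#' @param z_star stage-1 objective value; the solution satisfies
#'   objective >= `z_star` (up to feasibility tolerance)
#' @param fixed named numeric vector of fixed column values
#' @param exterior_weight weight on non-internal columns (default `1e-8`)
#' @return a `flux_state`
#' @export
minimize_norm <- function(system, z_star, fixed = NULL, exterior_weight = 1e-8) {
  bb <- assemble_bounds(system, fixed)
  A <- as.matrix(system$S)
  w <- ifelse(system$cols$internal, 1, exterior_weight)
  slack <- FEAS_TOL * max(1, abs(z_star))
  r <- qp_weighted_norm(w, A, rep(0, nrow(A)), bb$lb, bb$ub,
                        G = matrix(system$obj, nrow = 1),
                        h = z_star - slack)
  if (!identical(r$status, "optimal"))
    return(new_flux_state(system, NULL, r$status))
  new_flux_state(system, r$x, "optimal")
}

#' Normal-state solve: stage 1 followed by stage 2
#'
#' @param system an `irreversible_system`
#' @param fixed named numeric vector of fixed column values
#' @return list with `z_star`, `stage1` and `state` (the stage-2
#'   `flux_state`); `state$status` is `"infeasible"`/`"unbounded"` and the
#'   other entries `NA` when stage 1 fails
#' @export
solve_two_stage <- function(system, fixed = NULL) {
  s1 <- maximize_objective(system, fixed)
  if (!identical(s1$status, "optimal"))
    return(list(z_star = NA_real_, stage1 = s1, state = s1))
  s2 <- minimize_norm(system, s1$z, fixed)
  list(z_star = s1$z, stage1 = s1, state = s2)
}

#' Flux range of columns at the normal state
#'
#' Minimal and maximal attainable flux of each requested column under the
#' steady-state constraints and bounds (`mode = "free"`), optionally with
#' the objective held at its optimum (`mode = "objective_fixed"`). The basal
#' flux is read off the supplied normal-state solution.
#'
#' @param system an `irreversible_system`
#' @param columns column ids (default: all columns)
#' @param mode `"free"` (default) or `"objective_fixed"`
#' @param z_star required when `mode = "objective_fixed"`
#' @param basal_state optional `flux_state` providing `v_basal`
#' @return data.frame (`col_id`, `v_min`, `v_max`, `v_basal`)
#' @export
flux_range <- function(system, columns = system$cols$col_id,
                       mode = c("free", "objective_fixed"),
                       z_star = NULL, basal_state = NULL) {
  mode <- match.arg(mode)
  idx <- match(columns, system$cols$col_id)
  if (anyNA(idx))
    stop("unknown column(s): ", paste(columns[is.na(idx)], collapse = ", "))
  A <- as.matrix(system$S)
  b <- rep(0, nrow(A))
  lb <- system$cols$lb; ub <- system$cols$ub
  ncol_s <- ncol(A)
  if (mode == "objective_fixed") {
    if (is.null(z_star)) stop("objective_fixed mode requires z_star")
    # add slack column s >= 0 with obj'v - s = z_star  <=>  obj'v >= z_star
    A <- cbind(rbind(A, system$obj), c(b * 0, 0))
    A[nrow(A), ncol(A)] <- -1
    b <- c(b, z_star - FEAS_TOL * max(1, abs(z_star)))
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  out <- data.frame(col_id = columns, v_min = NA_real_, v_max = NA_real_,
                    v_basal = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    cc <- numeric(ncol(A)); cc[idx[k]] <- 1
    rmin <- simplex_lp(cc, A, b, lb, ub, maximize = FALSE)
    rmax <- simplex_lp(cc, A, b, lb, ub, maximize = TRUE)
    if (!identical(rmin$status, "optimal"))
      stop("flux_range: system ", rmin$status, " when minimising ", columns[k])
    vmax <- if (identical(rmax$status, "unbounded")) Inf else if
              (identical(rmax$status, "optimal")) rmax$z else
              stop("flux_range: system ", rmax$status, " when maximising ", columns[k])
    out$v_min[k] <- if (abs(rmin$z) < ZERO_FLUX_TOL) 0 else rmin$z
    out$v_max[k] <- if (is.finite(vmax) && abs(vmax) < ZERO_FLUX_TOL) 0 else vmax
  }
  if (!is.null(basal_state)) {
    stopifnot(identical(basal_state$status, "optimal"))
    out$v_basal <- unname(basal_state$v[columns])
    # clamp basal into the range against roundoff at the boundary
    out$v_basal <- pmin(pmax(out$v_basal, out$v_min), out$v_max)
  }
  out
}

#' Mass-balance residual of a flux state
#'
#' @param system an `irreversible_system`
#' @param state an optimal `flux_state`
#' @return max over metabolites of |N (v_f - v_b)|
#' @export
balance_residual <- function(system, state) {
  stopifnot(identical(state$status, "optimal"))
  max(abs(as.vector(system$S %*% state$v)))
}
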