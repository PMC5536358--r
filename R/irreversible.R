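# Split every reaction into non-negative forward/backward flux columns.

#' Split a model into an irreversible forward/backward flux system
#'
#' Every reversible reaction contributes two non-negative columns whose
#' stoichiometries are negatives of each other; the net flux of the original
#' reaction is `v_f - v_b`. Bounds map so the original interval is exactly
#' representable: forward `(max(lb,0), max(ub,0))`, backward
#' `(max(-ub,0), max(-lb,0))`. Internal columns are those of non-exchange
#' reactions; they form the index set over which the flux-norm objective of
#' [minimize_norm()] is taken.
#'
#' When the model's objective is a metabolite, an irreversible demand column
#' consuming one unit of it is used; if the model has no such demand
#' reaction one is appended (id `DM_<metabolite>`), flagged as an exchange
#' so it never enters the internal set.
#'
#' @param model a `metabolic_model` with an objective declared
#' @return object of class `irreversible_system`: the split stoichiometric
#'   matrix `S`, a `cols` data.frame (`col_id`, `reaction`, `dir`, `lb`,
#'   `ub`, `internal`), objective coefficients `obj`, and index maps
#'   `forward_index` / `backward_index` (reaction id -> column).
#' @export
split_reversible <- function(model) {
  if (is.null(model$objective))
    stop("model has no objective; set $objective before splitting")

  # materialise a demand reaction for a metabolite objective if absent
  obj_reaction <- model$objective$reaction
  if (!is.null(model$objective$metabolite)) {
    met <- model$objective$metabolite
    dm_id <- paste0("DM_", met)
    if (!dm_id %in% model$reactions$id) {
      # rebuild with the appended demand column
      rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
        st <- model$stoich[, k]
        list(id = model$reactions$id[k], stoich = st[st != 0],
             lb = model$reactions$lb[k], ub = model$reactions$ub[k],
             reversible = model$reactions$reversible[k],
             genes = model$genes[[k]],
             exchange = model$reactions$exchange[k])
      })
      rxns[[length(rxns) + 1L]] <- list(
        id = dm_id, stoich = stats::setNames(-1, met),
        lb = 0, ub = Inf, reversible = FALSE,
        genes = character(0), exchange = TRUE)
      model <- metabolic_model(model$metabolites, rxns,
                               objective = model$objective,
                               compartments = model$compartments,
                               boundary_compartment = model$boundary_compartment)
    }
    obj_reaction <- dm_id
  }

  n <- nrow(model$reactions)
  rev <- model$reactions$reversible
  lb <- model$reactions$lb; ub <- model$reactions$ub
  bad <- which(lb > 0 & ub < 0)
  if (length(bad))
    stop("contradictory bounds (lb > 0 and ub < 0) on: ",
         paste(model$reactions$id[bad], collapse = ", "))

  fwd_cols <- seq_len(n)
  bwd_of <- which(rev)
  col_rxn <- c(model$reactions$id, model$reactions$id[bwd_of])
  col_dir <- c(rep("f", n), rep("b", length(bwd_of)))
  col_id <- paste0(col_rxn, "_", col_dir)
  col_lb <- c(pmax(lb, 0), pmax(-ub[bwd_of], 0))
  col_ub <- c(pmax(ub, 0), pmax(-lb[bwd_of], 0))
  internal <- c(!model$reactions$exchange, !model$reactions$exchange[bwd_of])

  S <- cbind(model$stoich, -model$stoich[, bwd_of, drop = FALSE])
  colnames(S) <- col_id

  obj <- numeric(length(col_id))
  oi <- match(obj_reaction, model$reactions$id)
  if (is.na(oi)) stop("objective reaction '", obj_reaction, "' not in model")
  obj[oi] <- 1
  if (rev[oi]) obj[n + match(oi, bwd_of)] <- -1   # net objective flux

  structure(list(
    S = S,
    cols = data.frame(col_id = col_id, reaction = col_rxn, dir = col_dir,
                      lb = col_lb, ub = col_ub, internal = internal,
                      stringsAsFactors = FALSE),
    obj = obj,
    forward_index = stats::setNames(fwd_cols, model$reactions$id),
    backward_index = stats::setNames(n + seq_along(bwd_of),
                                     model$reactions$id[bwd_of]),
    objective_reaction = obj_reaction,
    model = model), class = "irreversible_system")
}

#' @export
print.irreversible_system <- function(x, ...) {
  cat("irreversible_system: ", nrow(x$S), " metabolites x ", ncol(x$S),
      " columns (", sum(x$cols$dir == "b"), " backward; ",
      sum(x$cols$internal), " internal)\n", sep = "")
  cat("objective column(s) on reaction: ", x$objective_reaction, "\n", sep = "")
  invisible(x)
}

# columns (f and, when present, b) of one reaction
reaction_columns <- function(system, rid) {
  idx <- c(system$forward_index[rid],
           if (rid %in% names(system$backward_index))
             system$backward_index[rid])
  stats::setNames(unname(idx), system$cols$col_id[unname(idx)])
}

#' Net flux per original reaction from a split flux vector
#'
#' @param system an `irreversible_system`
#' @param v named flux vector over the split columns
#' @return named numeric vector over the original reaction ids
#' @export
net_fluxes <- function(system, v) {
  rids <- names(system$forward_index)
  out <- v[system$forward_index]
  bi <- system$backward_index
  out[match(names(bi), rids)] <- out[match(names(bi), rids)] - v[bi]
  stats::setNames(out, rids)
}
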