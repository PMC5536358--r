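# Compartmentalised metabolic model container and its invariants.

#' Construct a compartmentalised metabolic model
#'
#' The central container of the package: metabolites with compartment tags, a
#' sparse stoichiometric matrix, per-reaction flux bounds, flat gene labels,
#' and a declared objective (either a metabolite whose demand is maximised or
#' an explicit reaction).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one-letter code). `base_id` (the id with the compartment tag stripped)
#'   is derived if absent.
#' @param reactions list of reaction definitions; each element is a list with
#'   `id`, `stoich` (named numeric, metabolite id -> signed coefficient),
#'   `lb`, `ub`, `reversible`, and optionally `genes` (character vector) and
#'   `exchange` (logical; detected from the stoichiometry when omitted).
#' @param objective list with exactly one of `metabolite` or `reaction`
#'   naming the optimisation target, or `NULL` to set it later.
#' @param compartments character vector of compartment codes; defaults to
#'   those appearing in `metabolites`.
#' @param boundary_compartment one-letter code of the extracellular/boundary
#'   compartment, used for exchange detection and excluded from
#'   production-rate sums. Default `"e"`.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            compartments = NULL, boundary_compartment = "e") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$base_id))
    metabolites$base_id <- strip_compartment(metabolites$id, metabolites$compartment)
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))
  bad_cmp <- setdiff(metabolites$compartment, compartments)
  if (length(bad_cmp))
    stop("metabolite compartment(s) not in declared set: ",
         paste(bad_cmp, collapse = ", "))

  if (length(reactions) == 0L) stop("model has no reactions")
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  met_idx <- stats::setNames(seq_len(nrow(metabolites)), metabolites$id)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rx <- data.frame(id = ids, lb = NA_real_, ub = NA_real_,
                   reversible = NA, exchange = NA, stringsAsFactors = FALSE)
  genes <- vector("list", length(reactions)); names(genes) <- ids
  for (k in seq_along(reactions)) {
    r <- reactions[[k]]
    st <- r$stoich
    if (is.null(st) || length(st) == 0L)
      stop("reaction '", r$id, "' has empty stoichiometry")
    if (any(st == 0))
      stop("reaction '", r$id, "' has zero coefficient(s)")
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (is.null(r$lb) || is.null(r$ub) || is.na(r$lb) || is.na(r$ub))
      stop("reaction '", r$id, "' is missing flux bounds")
    if (r$lb > r$ub)
      stop("reaction '", r$id, "' has lb > ub")
    rev <- isTRUE(r$reversible)
    if (!rev && r$lb < 0)
      stop("irreversible reaction '", r$id, "' has negative lower bound")
    trip_i <- c(trip_i, met_idx[names(st)])
    trip_j <- c(trip_j, rep.int(k, length(st)))
    trip_x <- c(trip_x, unname(st))
    rx$lb[k] <- r$lb; rx$ub[k] <- r$ub; rx$reversible[k] <- rev
    genes[[k]] <- as.character(r$genes %||% character(0))
    ex <- r$exchange
    if (is.null(ex)) {
      cmp <- metabolites$compartment[met_idx[names(st)]]
      ex <- all(st > 0) || all(st < 0) || all(cmp == boundary_compartment)
    }
    rx$exchange[k] <- isTRUE(ex)
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(metabolites), length(reactions)),
                            dimnames = list(metabolites$id, ids))

  if (!is.null(objective)) {
    has_m <- !is.null(objective$metabolite); has_r <- !is.null(objective$reaction)
    if (has_m == has_r)
      stop("objective must name exactly one of 'metabolite' or 'reaction'")
    if (has_m && !objective$metabolite %in% metabolites$id)
      stop("objective metabolite '", objective$metabolite, "' not in model")
    if (has_r && !objective$reaction %in% ids)
      stop("objective reaction '", objective$reaction, "' not in model")
  }

  structure(list(metabolites = metabolites, reactions = rx, stoich = S,
                 genes = genes, compartments = compartments,
                 boundary_compartment = boundary_compartment,
                 objective = objective),
            class = "metabolic_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip "[c]" bracket or "_c" suffix compartment tags (Recon-style dialects).
strip_compartment <- function(id, compartment) {
  out <- id
  br <- paste0("\\[", compartment, "\\]$")
  sf <- paste0("_", compartment, "$")
  for (k in seq_along(id)) {
    if (grepl(br[k], id[k])) out[k] <- sub(br[k], "", id[k])
    else if (grepl(sf[k], id[k])) out[k] <- sub(sf[k], "", id[k])
  }
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model: ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ",
      length(x$compartments), " compartments (",
      paste(x$compartments, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$objective)) {
    tgt <- x$objective$metabolite %||% x$objective$reaction
    kind <- if (!is.null(x$objective$metabolite)) "metabolite" else "reaction"
    cat("objective ", kind, ": ", tgt, "\n", sep = "")
  }
  invisible(x)
}

#' Reactions carrying a given gene label
#'
#' Flat gene-to-reaction lookup (no boolean gene-protein-reaction logic):
#' returns, in model order, every reaction whose gene list contains `gene`.
#' An unknown gene yields an empty vector, not an error.
#'
#' @param model a `metabolic_model`
#' @param gene gene identifier
#' @return character vector of reaction ids (possibly empty)
#' @export
gene_to_reactions <- function(model, gene) {
  hit <- vapply(model$genes, function(g) gene %in% g, logical(1))
  model$reactions$id[hit]
}

#' All gene labels present in a model
#' @param model a `metabolic_model`
#' @return sorted character vector
#' @export
model_genes <- function(model) sort(unique(unlist(model$genes)))

#' Medium specification
#'
#' Exchange-reaction bounds describing the growth medium/diet. Uptake bounds
#' are non-negative magnitudes (the maximal inward flux of the named exchange
#' reaction); secretion bounds are (lower, upper) pairs on the outward flux,
#' allowing a forced minimal secretion such as the bilirubin constraint.
#'
#' @param uptake named numeric vector, exchange reaction id -> maximal uptake
#' @param secretion named list, exchange reaction id -> c(lower, upper)
#' @return object of class `medium_spec`
#' @export
medium_spec <- function(uptake = numeric(0), secretion = list()) {
  if (length(uptake)) {
    stopifnot(!is.null(names(uptake)), all(nzchar(names(uptake))))
    if (any(!is.finite(uptake)) || any(uptake < 0))
      stop("uptake bounds must be finite and non-negative")
  }
  for (nm in names(secretion)) {
    p <- secretion[[nm]]
    if (length(p) != 2L || any(!is.finite(p)) || p[1] > p[2] || any(p < 0))
      stop("secretion bound for '", nm,
           "' must be a finite non-negative (lower, upper) pair")
  }
  structure(list(uptake = uptake, secretion = secretion), class = "medium_spec")
}

#' Read a medium specification from TSV
#'
#' Expects columns `exchange_id`, `lower`, `upper` on the signed exchange
#' flux (negative = uptake). A negative `lower` declares the uptake
#' magnitude; a non-negative pair declares secretion bounds.
#'
#' @param path TSV file path
#' @return a `medium_spec`
#' @export
read_medium_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "lower", "upper") %in% names(d)))
  uptake <- numeric(0); secretion <- list()
  for (k in seq_len(nrow(d))) {
    if (d$lower[k] < 0) uptake[d$exchange_id[k]] <- -d$lower[k]
    else secretion[[d$exchange_id[k]]] <- c(d$lower[k], d$upper[k])
  }
  medium_spec(uptake, secretion)
}

# +1 if the forward direction of an exchange reaction exports (coefficient of
# its metabolite is negative, the usual "EX_x: x ->" convention), else -1.
exchange_orientation <- function(model, rid) {
  st <- model$stoich[, rid]
  st <- st[st != 0]
  if (all(st < 0)) 1 else if (all(st > 0)) -1 else 1
}

#' Apply a medium to a model
#'
#' Implements a minimal-medium policy: the uptake direction of every exchange
#' reaction not named in the medium is closed; named uptakes receive the
#' specified maximal inward flux; secretion pairs are applied as (lower,
#' upper) on the outward flux; secretion directions not named stay open.
#'
#' @param model a `metabolic_model`
#' @param medium a `medium_spec`
#' @return the modified `metabolic_model`
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  ex_ids <- model$reactions$id[model$reactions$exchange]
  unknown <- setdiff(c(names(medium$uptake), names(medium$secretion)), ex_ids)
  if (length(unknown))
    stop("medium names unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  for (rid in ex_ids) {
    k <- match(rid, model$reactions$id)
    orient <- exchange_orientation(model, rid)
    up <- medium$uptake[rid]
    up <- if (rid %in% names(medium$uptake)) unname(up) else 0
    if (orient == 1) {                       # forward = secretion, backward = uptake
      model$reactions$lb[k] <- -up
      if (up > 0) model$reactions$reversible[k] <- TRUE
    } else {
      model$reactions$ub[k] <- up
    }
    if (rid %in% names(medium$secretion)) {
      p <- medium$secretion[[rid]]
      if (orient == 1) {
        model$reactions$lb[k] <- p[1]; model$reactions$ub[k] <- p[2]
      } else {
        model$reactions$lb[k] <- -p[2]; model$reactions$ub[k] <- -p[1]
        model$reactions$reversible[k] <- TRUE
      }
    }
  }
  model
}

#' Close every uptake in a model
#'
#' Convenience for the zero-medium property: with all uptakes closed, a
#' mass-balanced model without internal sources supports no objective flux.
#'
#' @param model a `metabolic_model`
#' @return the modified model
#' @export
close_all_uptakes <- function(model) apply_medium(model, medium_spec())
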