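# SBML import (Level 2 and Level 3 with the FBC extension).
#
# A focused reader for the constraint-based subset of SBML that flux models
# actually use: compartments, species (with boundaryCondition), reactions
# with reactant/product stoichiometries, flux bounds (kineticLaw parameters
# in L2, fbc flux-bound parameters in L3), flat gene labels (GENE_ASSOCIATION
# notes in L2, fbc:geneProductAssociation in L3), and the active fbc
# objective. Kinetics, rules, events and units are out of scope.

#' Load a metabolic model from SBML
#'
#' @param path SBML file (Level 2, or Level 3 with/without FBC v2)
#' @param boundary_compartment compartment code treated as the system
#'   boundary; when `NULL` (default) it is guessed as the compartment whose
#'   id or name contains "extracellular"/"external", falling back to `"e"`.
#' @param default_bound when `strict_bounds = FALSE`, reactions without
#'   declared bounds receive (−default_bound, default_bound) if reversible
#'   and (0, default_bound) otherwise.
#' @param strict_bounds error on reactions without declared bounds (listing
#'   their ids) instead of applying `default_bound`. Default `TRUE`.
#' @return a `metabolic_model`
#' @export
load_sbml <- function(path, boundary_compartment = NULL,
                      default_bound = 1000, strict_bounds = TRUE) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  # namespace-agnostic navigation: SBML core and fbc elements are matched by
  # local name so L2, L3 and fbc prefixes all resolve the same way
  lpath <- function(path) {
    parts <- strsplit(sub("^\\.?/+", "", path), "/+")[[1]]
    prefix <- if (startsWith(path, ".//")) ".//" else "./"
    paste0(prefix, paste(sprintf("*[local-name()='%s']", parts),
                         collapse = "/"))
  }
  find1 <- function(x, path) xml2::xml_find_first(x, lpath(path))
  findall <- function(x, path) xml2::xml_find_all(x, lpath(path))
  # attribute lookups tolerate both prefixed and bare spellings
  attr2 <- function(nd, name) {
    v <- xml2::xml_attr(nd, name)
    miss <- is.na(v)
    if (any(miss)) {
      bare <- sub("^[a-zA-Z0-9]+:", "", name)
      if (bare != name) v[miss] <- xml2::xml_attr(nd, bare)[miss]
    }
    v
  }
  model_node <- find1(doc, ".//model")
  if (inherits(model_node, "xml_missing"))
    stop("malformed SBML: no <model> element in '", path, "'")

  comp_nodes <- findall(model_node, "./listOfCompartments/compartment")
  comps <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
                  xml2::xml_attr(comp_nodes, "id"),
                  xml2::xml_attr(comp_nodes, "name")),
    stringsAsFactors = FALSE)
  if (nrow(comps) == 0L) stop("malformed SBML: no compartments declared")
  # map possibly long compartment ids to the one-letter codes the rest of the
  # package uses; ids that are already single letters pass through
  code <- ifelse(nchar(comps$id) == 1L, comps$id,
                 substr(tolower(comps$name), 1L, 1L))
  code <- make.unique(code, sep = "")
  comp_code <- stats::setNames(code, comps$id)

  if (is.null(boundary_compartment)) {
    hit <- grepl("extracell|external|boundary", tolower(paste(comps$id, comps$name)))
    boundary_compartment <- if (any(hit)) comp_code[which(hit)[1]] else "e"
  }

  sp_nodes <- findall(model_node, "./listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("malformed SBML: no species declared")
  sp <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = unname(comp_code[xml2::xml_attr(sp_nodes, "compartment")]),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  if (anyNA(sp$compartment))
    stop("species reference undeclared compartment(s): ",
         paste(sp$id[is.na(sp$compartment)], collapse = ", "))

  # L3/FBC global flux-bound parameters
  par_nodes <- findall(model_node, "./listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- findall(model_node, "./listOfReactions/reaction")
  if (length(rx_nodes) == 0L) stop("model has no reactions")
  missing_bounds <- character(0)
  boundary_species <- sp$id[sp$boundary]
  rxns <- vector("list", length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    nd <- rx_nodes[[k]]
    rid <- xml2::xml_attr(nd, "id")
    rev <- !(xml2::xml_attr(nd, "reversible") %in% "false")
    sref <- function(xp, sign) {
      refs <- findall(nd, xp)
      if (length(refs) == 0L) return(numeric(0))
      v <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      v[is.na(v)] <- 1
      stats::setNames(sign * v, xml2::xml_attr(refs, "species"))
    }
    st <- c(sref("./listOfReactants/speciesReference", -1),
            sref("./listOfProducts/speciesReference", +1))
    if (length(st) == 0L)
      stop("malformed SBML: reaction '", rid, "' has no species references")
    # collapse duplicated species entries
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    involves_boundary_sp <- any(names(st) %in% boundary_species)
    st <- st[!names(st) %in% boundary_species & st != 0]

    lbv <- ubv <- NA_real_
    lb_ref <- attr2(nd, "fbc:lowerFluxBound")
    ub_ref <- attr2(nd, "fbc:upperFluxBound")
    if (!is.na(lb_ref)) lbv <- unname(par_val[lb_ref])
    if (!is.na(ub_ref)) ubv <- unname(par_val[ub_ref])
    if (is.na(lbv) || is.na(ubv)) {
      kl <- findall(nd, "./kineticLaw/listOfParameters/parameter")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kvl <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lbv) && "LOWER_BOUND" %in% kid) lbv <- kvl[match("LOWER_BOUND", kid)]
        if (is.na(ubv) && "UPPER_BOUND" %in% kid) ubv <- kvl[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lbv) || is.na(ubv)) {
      if (strict_bounds) missing_bounds <- c(missing_bounds, rid)
      else { if (is.na(lbv)) lbv <- if (rev) -default_bound else 0
             if (is.na(ubv)) ubv <- default_bound }
    }

    genes <- character(0)
    gpr <- findall(nd, ".//geneProductRef")
    if (length(gpr)) genes <- unique(attr2(gpr, "fbc:geneProduct"))
    if (!length(genes)) {
      notes <- xml2::xml_text(find1(nd, "./notes"))
      if (!is.na(notes) && grepl("GENE_ASSOCIATION", notes)) {
        ga <- sub(".*GENE_ASSOCIATION:\\s*([^\n<]*).*", "\\1", notes)
        genes <- unique(setdiff(
          strsplit(gsub("[()]", " ", ga), "\\s+(and|or|AND|OR)\\s+|\\s+")[[1]], ""))
      }
    }
    rxns[[k]] <- list(id = rid, stoich = st, lb = lbv, ub = ubv,
                      reversible = rev, genes = genes,
                      exchange = if (involves_boundary_sp) TRUE else NULL)
  }
  if (length(missing_bounds))
    stop("reaction(s) missing flux bounds: ",
         paste(missing_bounds, collapse = ", "))

  # gene product label -> name mapping (FBC): prefer labels over internal ids
  gp <- findall(model_node, ".//geneProduct")
  if (length(gp)) {
    lab <- attr2(gp, "fbc:label")
    gid <- attr2(gp, "fbc:id")
    ok <- !is.na(lab) & !is.na(gid)
    if (any(ok)) {
      map <- stats::setNames(lab[ok], gid[ok])
      rxns <- lapply(rxns, function(r) {
        hit <- r$genes %in% names(map)
        r$genes[hit] <- unname(map[r$genes[hit]])
        r })
    }
  }

  objective <- NULL
  fo <- find1(model_node, ".//fluxObjective")
  if (!inherits(fo, "xml_missing") && !is.na(attr2(fo, "fbc:reaction")))
    objective <- list(reaction = attr2(fo, "fbc:reaction"))

  sp_used <- sp[!sp$boundary, c("id", "name", "compartment")]
  metabolic_model(sp_used, rxns, objective = objective,
                  compartments = unique(sp_used$compartment),
                  boundary_compartment = boundary_compartment)
}
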