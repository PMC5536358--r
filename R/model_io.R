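# Tabular model dialect: a JSON document and an equivalent two-file TSV form.

#' Write a model in the tabular JSON dialect
#'
#' The dialect is a single JSON document:
#' `{"metabolites": [{id, name, compartment}], "reactions": [{id, stoich:
#' {met: coeff}, lb, ub, reversible, genes, exchange}], "objective":
#' {"metabolite": id} | {"reaction": id}, "compartments": [...],
#' "boundary_compartment": code}`.
#'
#' @param model a `metabolic_model`
#' @param path output file path
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(k)
    list(id = model$metabolites$id[k],
         name = model$metabolites$name[k],
         compartment = model$metabolites$compartment[k]))
  rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
    st <- model$stoich[, k]
    st <- st[st != 0]
    list(id = model$reactions$id[k],
         stoich = as.list(st),
         lb = model$reactions$lb[k], ub = model$reactions$ub[k],
         reversible = model$reactions$reversible[k],
         genes = model$genes[[k]],
         exchange = model$reactions$exchange[k])
  })
  doc <- list(metabolites = mets, reactions = rxns,
              objective = model$objective,
              compartments = model$compartments,
              boundary_compartment = model$boundary_compartment)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from the tabular JSON dialect
#'
#' Reaction and metabolite order follows the input document. Duplicate ids,
#' references to undeclared metabolites and an empty reaction list are
#' rejected with errors naming the offender.
#'
#' @param path JSON file path
#' @return a `metabolic_model`
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$reactions) || length(doc$reactions) == 0L)
    stop("model has no reactions")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- lapply(doc$reactions, function(r)
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = r$lb, ub = r$ub,
         reversible = isTRUE(r$reversible),
         genes = unlist(r$genes) %||% character(0),
         exchange = r$exchange))
  metabolic_model(mets, rxns, objective = doc$objective,
                  compartments = unlist(doc$compartments),
                  boundary_compartment = doc$boundary_compartment %||% "e")
}

# stoichiometry <-> compact "met:coeff;met:coeff" text encoding for the TSV form
encode_stoich <- function(st) paste(sprintf("%s:%.15g", names(st), unname(st)),
                                    collapse = ";")
decode_stoich <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(kv, `[`, character(1), 1))
}

#' Write a model in the two-file TSV form
#'
#' `<stem>_metabolites.tsv` holds id/name/compartment; `<stem>_reactions.tsv`
#' holds id, a `met:coeff;met:coeff` stoichiometry column, bounds,
#' reversibility, semicolon-joined genes and the exchange flag. The objective
#' is carried as an `objective` column marking its target row (or a leading
#' `#objective metabolite <id>` comment line when the target is a metabolite).
#'
#' @param model a `metabolic_model`
#' @param stem path stem for the two files
#' @return invisibly, the two file paths
#' @export
write_model_tsv <- function(model, stem) {
  mp <- paste0(stem, "_metabolites.tsv")
  rp <- paste0(stem, "_reactions.tsv")
  utils::write.table(model$metabolites[, c("id", "name", "compartment")],
                     mp, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- data.frame(
    id = model$reactions$id,
    stoich = vapply(seq_len(nrow(model$reactions)), function(k) {
      st <- model$stoich[, k]; encode_stoich(st[st != 0])
    }, character(1)),
    lb = model$reactions$lb, ub = model$reactions$ub,
    reversible = model$reactions$reversible,
    genes = vapply(model$genes, paste, character(1), collapse = ";"),
    exchange = model$reactions$exchange,
    stringsAsFactors = FALSE)
  con <- file(rp, "w"); on.exit(close(con))
  if (!is.null(model$objective)) {
    kind <- if (!is.null(model$objective$metabolite)) "metabolite" else "reaction"
    writeLines(sprintf("#objective %s %s", kind,
                       model$objective[[kind]]), con)
  }
  writeLines(sprintf("#boundary_compartment %s", model$boundary_compartment), con)
  utils::write.table(rd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mp, rp))
}

#' Read a model from the two-file TSV form
#'
#' @param stem path stem used by [write_model_tsv()]
#' @return a `metabolic_model`
#' @export
read_model_tsv <- function(stem) {
  mp <- paste0(stem, "_metabolites.tsv")
  rp <- paste0(stem, "_reactions.tsv")
  mets <- utils::read.delim(mp, stringsAsFactors = FALSE, comment.char = "")
  hdr <- readLines(rp, n = 5L)
  objective <- NULL; boundary <- "e"
  for (line in hdr[startsWith(hdr, "#")]) {
    f <- strsplit(sub("^#", "", line), " +")[[1]]
    if (f[1] == "objective") objective <- stats::setNames(list(f[3]), f[2])
    if (f[1] == "boundary_compartment") boundary <- f[2]
  }
  rd <- utils::read.delim(rp, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(rd) == 0L) stop("model has no reactions")
  rxns <- lapply(seq_len(nrow(rd)), function(k)
    list(id = rd$id[k], stoich = decode_stoich(rd$stoich[k]),
         lb = rd$lb[k], ub = rd$ub[k], reversible = rd$reversible[k],
         genes = if (nzchar(rd$genes[k]))
           strsplit(rd$genes[k], ";", fixed = TRUE)[[1]] else character(0),
         exchange = rd$exchange[k]))
  metabolic_model(mets, rxns, objective = objective,
                  boundary_compartment = boundary)
}
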